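# Independent brute-force oracles and random-input generators used across
# the suite. These re-derive expected values from first principles with
# naive loops, separately from the package's implementations.

suppressMessages(library(data.table))
options(episplice.verbose = FALSE)

# ---- random gene models ----------------------------------------------------

# A random multi-transcript gene: a scaffold of exons perturbed per
# transcript by exon skipping, boundary shifts and intron-retention merges,
# so all event types arise by chance.
random_gene <- function(gid, n_tx = sample(2:4, 1), strand = sample(c("+", "-"), 1)) {
  n_ex <- sample(5:8, 1)
  lens <- sample(80:250, n_ex, replace = TRUE)
  gaps <- sample(200:600, n_ex - 1, replace = TRUE)
  starts <- cumsum(c(1000, lens[-n_ex] + gaps))
  scaffold <- cbind(starts, starts + lens)
  txs <- list()
  for (i in seq_len(n_tx)) {
    ex <- scaffold
    k <- 2L
    while (k <= n_ex - 1L) {
      r <- runif(1)
      if (!is.na(ex[k, 1])) {
        if (r < 0.15) {
          ex[k, ] <- NA
        } else if (r < 0.25) {
          ex[k, 1] <- ex[k, 1] + sample(c(-60, -30, 30, 60), 1)
        } else if (r < 0.35) {
          ex[k, 2] <- ex[k, 2] + sample(c(-60, -30, 30, 60), 1)
        } else if (r < 0.42 && k < n_ex - 1L && !is.na(ex[k + 1L, 1])) {
          ex[k, 2] <- ex[k + 1L, 2]
          ex[k + 1L, ] <- NA
          k <- k + 1L
        }
      }
      k <- k + 1L
    }
    ex <- ex[!is.na(ex[, 1]), , drop = FALSE]
    txs[[i]] <- new_transcript(sprintf("%s.t%d", gid, i), gid, "chrR",
                               strand, ex)
  }
  new_gene(gid, "chrR", strand, txs)
}

# ---- brute-force event classifier ------------------------------------------

# Enumerates exon pairs/triples of every ordered transcript pair and applies
# the event predicates written out longhand; returns unique
# "type:sorted-coords" keys.
oracle_classify <- function(g) {
  txs <- g$transcripts
  keys <- character(0)
  add <- function(type, coords) {
    keys <<- c(keys, paste(type, paste(sort(unique(coords)), collapse = ","),
                           sep = ":"))
  }
  for (a in seq_along(txs)) {
    for (b in seq_along(txs)) {
      if (a == b) next
      A <- txs[[a]]$exons
      B <- txs[[b]]$exons
      nA <- nrow(A); nB <- nrow(B)
      if (nA < 3L) next
      junB <- if (nB >= 2L) paste(B[-nB, 2], B[-1L, 1]) else character(0)
      for (k in 2:(nA - 1L)) {
        s <- A[k, 1]; e <- A[k, 2]
        pe <- A[k - 1L, 2]; ns <- A[k + 1L, 1]
        if (paste(pe, ns) %in% junB && !any(B[, 1] < e & B[, 2] > s)) {
          add("ES", c(s, e))
        }
        if (nB >= 3L) {
          for (l in 2:(nB - 1L)) {
            s2 <- B[l, 1]; e2 <- B[l, 2]
            pe2 <- B[l - 1L, 2]; ns2 <- B[l + 1L, 1]
            ov <- s < e2 && s2 < e
            if (!ov && pe2 == pe && ns2 == ns &&
                !any(B[, 1] == s & B[, 2] == e) &&
                !any(A[, 1] == s2 & A[, 2] == e2)) {
              add("ME", c(s, e, s2, e2))
            }
            if (ov && e == e2 && s != s2 && pe == pe2) {
              add(if (g$strand == "+") "A3SS" else "A5SS", c(s, e, s2, e2))
            }
            if (ov && s == s2 && e != e2 && ns == ns2) {
              add(if (g$strand == "+") "A5SS" else "A3SS", c(s, e, s2, e2))
            }
          }
        }
        if (nB >= 2L) {
          for (m in 1:(nB - 1L)) {
            if (B[m, 1] == s && B[m + 1L, 2] == e) {
              add("IR", c(B[m, 2], B[m + 1L, 1]))
            }
          }
        }
      }
    }
  }
  sort(unique(keys))
}

# CNE oracle: internal exons present (and internal) in every transcript
# whose span covers them, minus exons named in any oracle event key.
oracle_cne <- function(g, event_keys) {
  used <- unique(unlist(lapply(strsplit(sub("^[^:]+:", "", event_keys), ","),
                               as.numeric)))
  keys <- character(0)
  for (t in g$transcripts) {
    n <- nrow(t$exons)
    if (n <= 2L) next
    for (k in 2:(n - 1L)) {
      s <- t$exons[k, 1]; e <- t$exons[k, 2]
      ok <- TRUE
      for (u in g$transcripts) {
        sp <- c(u$exons[1, 1], u$exons[nrow(u$exons), 2])
        if (sp[1] <= s && sp[2] >= e) {
          m <- which(u$exons[, 1] == s & u$exons[, 2] == e)
          if (length(m) != 1L || m == 1L || m == nrow(u$exons)) {
            ok <- FALSE
            break
          }
        }
      }
      # an exon sharing any boundary with an event's site tuple may still be
      # constitutive; participation means the exon's own pair was used
      if (ok && !participates(s, e, event_keys)) {
        keys <- c(keys, paste("CNE", paste(s, e, sep = ","), sep = ":"))
      }
    }
  }
  sort(unique(keys))
}

participates <- function(s, e, event_keys) {
  for (key in event_keys) {
    type <- sub(":.*$", "", key)
    coords <- as.numeric(strsplit(sub("^[^:]+:", "", key), ",")[[1]])
    if (type == "IR") {
      # IR keys carry the retained intron; participants are the spanning
      # exon and the two partner exons sharing these boundaries
      if (e == coords[1] || s == coords[2]) return(TRUE)
      if (s < coords[1] && e > coords[2]) return(TRUE)
    } else if (s %in% coords && e %in% coords) {
      # ES keys are one exon; ME/A3SS/A5SS keys hold both exons' boundaries
      return(TRUE)
    }
  }
  FALSE
}

# Implementation events -> comparable keys (drop the chrom component).
impl_event_keys <- function(events) {
  sort(unique(sub("^([^:]+):[^:]+:", "\\1:", events$site_key)))
}

# ---- naive signal oracles --------------------------------------------------

# Manual strand-directed extension of raw reads.
naive_extend <- function(dt, extension = 200) {
  out <- copy(as.data.table(dt))
  plus <- out$strand == "+"
  out[plus, end := start + extension]
  out[!plus, start := pmax(end - extension, 0)]
  out
}

naive_read_count <- function(ext_dt, s, e) {
  sum(ext_dt$start < e & ext_dt$end > s)
}

naive_coverage <- function(ext_dt, s, e) {
  vapply(s:(e - 1), function(p) sum(ext_dt$start <= p & ext_dt$end > p),
         numeric(1))
}

naive_meth_pct <- function(sites_dt, s, e) {
  sub <- sites_dt[sites_dt$pos >= s & sites_dt$pos + 2 <= e, ]
  if (nrow(sub) == 0L) return(list(percentage = NA_real_, n_sites = 0L))
  list(percentage = 100 * mean(sub$methylated), n_sites = nrow(sub))
}

naive_moving_average <- function(x, window) {
  h <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

# Welch one-tailed p from the textbook formulas.
welch_one_tailed_p <- function(a, b) {
  v1 <- var(a) / length(a)
  v2 <- var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(a) - 1) + v2^2 / (length(b) - 1))
  if (tstat >= 0) pt(tstat, df, lower.tail = FALSE) else pt(tstat, df)
}

# ---- strand-flip utilities -------------------------------------------------

flip_gene <- function(g, L) {
  strand <- if (g$strand == "+") "-" else "+"
  txs <- lapply(g$transcripts, function(t) {
    ex <- cbind(L - t$exons[, "end"], L - t$exons[, "start"])
    new_transcript(t$transcript_id, t$gene_id, t$chrom, strand, ex,
                   coding = t$coding)
  })
  new_gene(g$gene_id, g$chrom, strand, txs)
}

flip_raw_reads <- function(dt, L) {
  out <- copy(as.data.table(dt))
  out[, `:=`(start2 = L - end, end2 = L - start,
             strand = ifelse(strand == "+", "-", "+"))]
  out[, `:=`(start = start2, end = end2, start2 = NULL, end2 = NULL)]
  out
}

flip_meth_sites <- function(dt, L) {
  out <- copy(as.data.table(dt))
  out[, pos := L - pos - 2]  # CpG maps onto CpG under reverse complement
  out
}

# ---- misc -------------------------------------------------------------------

# Adjusted Rand index between two labelings.
adjusted_rand_index <- function(x, y) {
  tab <- table(x, y)
  ch2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_i <- sum(ch2(rowSums(tab)))
  sum_j <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  expected <- sum_i * sum_j / n
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}

# Small deterministic read track as a data.table.
random_reads <- function(n, L, read_length = 36) {
  data.table(chrom = "chrR",
             start = sample.int(L - read_length, n, replace = TRUE) - 1L,
             end = 0L, strand = sample(c("+", "-"), n, replace = TRUE))[,
               end := start + read_length][]
}

# ---- clustering fixtures ---------------------------------------------------

archetype_matrix <- function(n_per = 3, noise_sd = 0.1, d = 20, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(10, 10), c(10, -10), c(-10, 10), c(-10, -10))
  base <- matrix(0, 4, d)
  base[, 1:2] <- centers
  rows <- do.call(rbind, lapply(1:4, function(a) {
    matrix(rep(base[a, ], n_per), nrow = n_per, byrow = TRUE) +
      matrix(rnorm(n_per * d, sd = noise_sd), n_per)
  }))
  rownames(rows) <- sprintf("f%02d", seq_len(nrow(rows)))
  list(x = rows, truth = rep(1:4, each = n_per))
}

sign_structured_matrix <- function(v = 3) {
  # ES/ME columns are negated copies of the A3SS/A5SS/IR columns
  feats <- sprintf("f%d", 1:6)
  cols <- as.vector(outer(c("acceptor_intronic", "acceptor_exonic",
                            "donor_exonic", "donor_intronic"),
                          c("ES", "ME", "A3SS", "A5SS", "IR"),
                          function(b, t) paste(t, b, sep = ".")))
  m <- matrix(0, 6, 20, dimnames = list(feats, cols))
  set.seed(9)
  base <- matrix(rnorm(6 * 4, sd = 0.2) + v, 6, 4)
  for (ty in c("ES", "ME")) m[, grep(paste0("^", ty), cols)] <- -base
  for (ty in c("A3SS", "A5SS", "IR")) m[, grep(paste0("^", ty), cols)] <- base
  m
}
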