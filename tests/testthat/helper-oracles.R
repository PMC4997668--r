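# Independent oracles used across the suite. These deliberately re-derive
# results by brute force (loops, eigen instead of svd, exhaustive
# agglomeration) so the package implementation is checked against a second
# route, not against itself.

# Wright's ENC computed loop-wise from a named RNA-codon count vector
oracle_enc <- function(counts) {
  code <- genetic_code()
  sense <- code[!is.na(code$family), ]
  fams <- split(sense$codon_rna, sense$family)
  f_class <- list(`2` = numeric(), `3` = numeric(),
                  `4` = numeric(), `6` = numeric())
  for (f in names(fams)) {
    cods <- fams[[f]]
    cnt <- counts[cods]
    cnt[is.na(cnt)] <- 0
    n <- sum(cnt)
    if (n < 2) next
    p <- cnt / n
    f_hat <- (n * sum(p^2) - 1) / (n - 1)
    if (f_hat <= 0) next
    k <- as.character(length(cods))
    f_class[[k]] <- c(f_class[[k]], f_hat)
  }
  f_bar <- vapply(f_class, function(v) if (length(v)) mean(v) else NA_real_,
                  numeric(1))
  if (is.na(f_bar[["3"]]) && !is.na(f_bar[["2"]]) && !is.na(f_bar[["4"]])) {
    f_bar[["3"]] <- mean(c(f_bar[["2"]], f_bar[["4"]]))
  }
  f_bar[is.na(f_bar)] <- mean(f_bar, na.rm = TRUE)
  value <- 2 + 9 / f_bar[["2"]] + 1 / f_bar[["3"]] +
    5 / f_bar[["4"]] + 3 / f_bar[["6"]]
  min(61, max(20, value))
}

# asymptotic (infinite-count) ENC: homozygosity taken as sum(p^2) exactly
oracle_enc_asymptotic <- function(counts) {
  code <- genetic_code()
  sense <- code[!is.na(code$family), ]
  fams <- split(sense$codon_rna, sense$family)
  f_class <- list(`2` = numeric(), `3` = numeric(),
                  `4` = numeric(), `6` = numeric())
  for (f in names(fams)) {
    cnt <- counts[fams[[f]]]
    cnt[is.na(cnt)] <- 0
    if (sum(cnt) == 0) next
    p <- cnt / sum(cnt)
    f_class[[as.character(length(cnt))]] <-
      c(f_class[[as.character(length(cnt))]], sum(p^2))
  }
  f_bar <- vapply(f_class, mean, numeric(1))
  min(61, max(20, 2 + 9 / f_bar[["2"]] + 1 / f_bar[["3"]] +
                5 / f_bar[["4"]] + 3 / f_bar[["6"]]))
}

# random positive counts over the 59 sense codons
random_sense_counts <- function(seed, lambda = 20) {
  set.seed(seed)
  sense <- sense_codons()
  counts <- stats::rpois(nrow(sense), lambda)
  stats::setNames(counts, sense$codon_rna)
}

counts_to_tbl <- function(counts, gene_id = "g") {
  tibble::tibble(gene_id = gene_id, codon = names(counts),
                 count = as.integer(counts))
}

# build a DNA CDS realising a codon count vector (RNA names), plus start/stop
seq_from_counts <- function(counts) {
  cods <- rep(names(counts), counts)
  paste0("ATG", paste(chartr("U", "T", cods), collapse = ""), "TAA")
}

# correspondence-analysis inertia fractions via an explicit eigen
# decomposition of the chi-square residual cross-product
oracle_ca_fractions <- function(x) {
  p <- x / sum(x)
  e <- outer(rowSums(p), colSums(p))
  s <- (p - e) / sqrt(e)
  ev <- eigen(crossprod(s), symmetric = TRUE)$values
  ev <- ev[ev > max(ev) * 1e-10]
  ev / sum(ev)
}

# exhaustive average-linkage agglomeration: returns sorted merge heights
oracle_average_link_heights <- function(d) {
  m <- as.matrix(d)
  members <- as.list(seq_len(nrow(m)))
  heights <- numeric()
  while (length(members) > 1L) {
    best <- Inf
    pick <- c(NA, NA)
    for (i in seq_along(members)) {
      for (j in seq_len(i - 1L)) {
        dd <- mean(m[members[[i]], members[[j]]])
        if (dd < best) {
          best <- dd
          pick <- c(i, j)
        }
      }
    }
    heights <- c(heights, best)
    members[[pick[2]]] <- c(members[[pick[2]]], members[[pick[1]]])
    members[[pick[1]]] <- NULL
  }
  sort(heights)
}

# mean silhouette of a 1-d embedding under a 2-group labelling
mean_silhouette_1d <- function(x, groups) {
  n <- length(x)
  sil <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(groups == groups[i] & seq_len(n) != i)
    other <- which(groups != groups[i])
    a <- mean(abs(x[i] - x[same]))
    b <- mean(abs(x[i] - x[other]))
    sil[i] <- (b - a) / max(a, b)
  }
  mean(sil)
}

# agreement of a 2-cluster labelling with planted groups, up to label swap
two_group_agreement <- function(cluster, truth) {
  truth <- as.integer(factor(truth))
  max(mean(cluster == truth), mean(cluster == 3L - truth))
}
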