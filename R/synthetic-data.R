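#' Define a codon-usage generative regime
#'
#' A regime describes how synthetic codon usage is produced: a third-position
#' GC pressure (`gc3_target`), a coupling coefficient tying first/second
#' position composition to that same pressure (`gc12_coupling`: 1 means all
#' three positions are driven together, as under directional mutation
#' pressure; 0 decouples them, as when selection fixes the protein while the
#' third position drifts), and a Dirichlet concentration (`family_skew`)
#' controlling within-family bias beyond the base pressure (smaller values
#' give stronger, more idiosyncratic codon preferences; `Inf` disables
#' skew).
#'
#' Named presets: `"mutation_dominated"` (coupling 1, negligible skew),
#' `"selection_dominated"` (coupling 0, moderate skew), `"uniform"` (even
#' synonymous usage), `"single_codon"` (one codon per family, maximal
#' bias), `"custom"`.
#'
#' @param name Regime name (see above).
#' @param gc3_target GC3 pressure as a fraction in (0, 1); a length-2
#'   vector gives the range spanned by a cohort's genes.
#' @param gc12_coupling Coupling coefficient in \[0, 1\]; default depends
#'   on `name`.
#' @param family_skew Dirichlet concentration (> 0, may be `Inf`); default
#'   depends on `name`.
#' @return An object of class `usage_regime`.
#' @examples
#' usage_regime("mutation_dominated", gc3_target = c(0.3, 0.8))
#' @export
usage_regime <- function(name = c("selection_dominated", "mutation_dominated",
                                  "uniform", "single_codon", "custom"),
                         gc3_target = 0.6, gc12_coupling = NULL,
                         family_skew = NULL) {
  name <- match.arg(name)
  defaults <- list(
    mutation_dominated = list(coupling = 1, skew = 200),
    selection_dominated = list(coupling = 0, skew = 4),
    uniform = list(coupling = 0, skew = Inf),
    single_codon = list(coupling = 0, skew = Inf),
    custom = list(coupling = 0.5, skew = 10)
  )[[name]]
  if (is.null(gc12_coupling)) gc12_coupling <- defaults$coupling
  if (is.null(family_skew)) family_skew <- defaults$skew
  stopifnot(all(gc3_target > 0 & gc3_target < 1),
            gc12_coupling >= 0, gc12_coupling <= 1, family_skew > 0)
  structure(list(name = name, gc3_target = gc3_target,
                 gc12_coupling = gc12_coupling, family_skew = family_skew),
            class = "usage_regime")
}

#' @export
print.usage_regime <- function(x, ...) {
  cat(sprintf(
    "usage_regime '%s': gc3_target %s, gc12_coupling %.2f, family_skew %s\n",
    x$name, paste(format(x$gc3_target), collapse = "-"),
    x$gc12_coupling, format(x$family_skew)))
  invisible(x)
}

# one Dirichlet skew draw per family (named vector over the 59 sense
# codons); concentration Inf means no skew
.draw_family_skew <- function(concentration) {
  code <- sense_codons()
  if (is.infinite(concentration)) {
    return(stats::setNames(rep(1, nrow(code)), code$codon))
  }
  skew <- unlist(lapply(split(code$codon, code$family), function(cods) {
    g <- stats::rgamma(length(cods), shape = concentration, rate = 1)
    stats::setNames(g / sum(g) * length(cods), cods)
  }))
  names(skew) <- sub("^[^.]+\\.", "", names(skew))
  skew[code$codon]
}

#' Per-family codon sampling distribution for a regime
#'
#' Builds the codon probabilities used by [generate_cds()]: within each
#' synonymous family, G/C-ending codons receive weight
#' `gc3_target / (number of G/C-ending synonyms)` and A/U-ending codons
#' `(1 - gc3_target) / (number of A/U-ending synonyms)`, multiplied by the
#' family-skew factor and renormalised per family. With this normalisation
#' the expected third-position GC fraction of every family equals
#' `gc3_target` exactly (before skew). `"uniform"` regimes give equal
#' probabilities; `"single_codon"` puts probability 1 on the
#' highest-pressure codon of each family (ties broken alphabetically).
#'
#' @param regime A [usage_regime()]; a scalar `gc3_target` is required
#'   (cohorts resolve ranges per gene before calling this).
#' @param skew Optional named skew vector over the 59 sense codons (as
#'   drawn internally from `Dirichlet(family_skew)`); when `NULL` and the
#'   regime has finite `family_skew`, a draw is taken from the current RNG
#'   stream.
#' @return Tibble `codon` (DNA), `family`, `prob` (summing to 1 within
#'   each family).
#' @export
build_codon_distribution <- function(regime, skew = NULL) {
  stopifnot(inherits(regime, "usage_regime"), length(regime$gc3_target) == 1L)
  code <- sense_codons()
  if (is.null(skew)) skew <- .draw_family_skew(regime$family_skew)
  stopifnot(all(code$codon %in% names(skew)))
  s <- regime$gc3_target
  rows <- lapply(split(code, code$family), function(f) {
    n_gc <- sum(f$gc_ending)
    n_au <- sum(!f$gc_ending)
    if (n_gc == 0L || n_au == 0L) {
      warning("family ", f$family[1], " lacks one third-base class; ",
              "renormalising within available codons", call. = FALSE)
      w <- rep(1, nrow(f))
    } else {
      w <- ifelse(f$gc_ending, s / n_gc, (1 - s) / n_au)
    }
    if (regime$name == "uniform") {
      p <- rep(1 / nrow(f), nrow(f))
    } else if (regime$name == "single_codon") {
      pick <- order(-w, f$codon)[1L]
      p <- as.numeric(seq_len(nrow(f)) == pick)
    } else if (n_gc == 0L || n_au == 0L) {
      sk <- skew[f$codon]
      p <- unname(w * sk / sum(w * sk))
    } else {
      # recalibrate the GC/AU split so the family's expected third-base GC
      # equals the target even after skew (skew redistributes only within
      # each third-base class)
      sk <- unname(skew[f$codon])
      a <- sum(sk[f$gc_ending] / n_gc)
      b <- sum(sk[!f$gc_ending] / n_au)
      x <- s * b / ((1 - s) * a)
      t_gc <- x / (1 + x)
      w <- ifelse(f$gc_ending, t_gc / n_gc, (1 - t_gc) / n_au) * sk
      p <- w / sum(w)
    }
    tibble::tibble(codon = f$codon, family = f$family[1], prob = unname(p))
  })
  dplyr::bind_rows(rows)
}

# expected G+C count over codon positions 1-2, per family, under a codon
# distribution
.family_gc12_load <- function(distribution) {
  gc12 <- function(codon) {
    sum(strsplit(substr(codon, 1, 2), "")[[1]] %in% c("G", "C"))
  }
  loads <- vapply(distribution$codon, gc12, numeric(1))
  tapply(distribution$prob * loads, distribution$family, sum) /
    tapply(distribution$prob, distribution$family, sum)
}

# solve for the position-1/2 pressure exponent p such that the expected
# GC12 under amino-acid reweighting equals target_gc12
.solve_aa_pressure <- function(aa_freq, g, target_gc12) {
  gc12_at <- function(p) {
    w <- aa_freq * p^g * (1 - p)^(2 - g)
    sum(w * g / 2) / sum(w)
  }
  lo <- 1e-4
  hi <- 1 - 1e-4
  if (target_gc12 <= gc12_at(lo)) return(lo)   # clamped to achievable range
  if (target_gc12 >= gc12_at(hi)) return(hi)
  stats::uniroot(function(p) gc12_at(p) - target_gc12, c(lo, hi),
                 tol = 1e-10)$root
}

#' Generate one synthetic coding sequence
#'
#' Draws an amino-acid sequence i.i.d. from the composition, then each
#' codon from its family's distribution; prepends AUG and appends a UAA
#' stop. When `gc12_coupling > 0`, amino-acid choice is reweighted towards
#' residues whose first/second codon positions match the third-position
#' pressure, calibrated (by root finding) so that the expected GC12 equals
#' `g0 + coupling * (gc3_target - g0)`, where `g0` is the baseline GC12 of
#' the unweighted composition — this makes the neutrality-plot slope of a
#' cohort equal the coupling coefficient in expectation.
#'
#' @param n_codons Total codon count of the CDS, including the added start
#'   and stop (so the nucleotide length is `3 * n_codons`).
#' @param distribution Codon distribution from [build_codon_distribution()].
#' @param aa_freq Named amino-acid frequencies over the 18 family names
#'   (default uniform).
#' @param gc12_coupling Coupling coefficient in \[0, 1\] (default 0).
#' @param gc3_target The regime's GC3 pressure (needed when coupling > 0).
#' @param seed Optional integer seed giving a reproducible draw without
#'   touching the caller's RNG stream.
#' @return The CDS as an uppercase DNA string.
#' @examples
#' dist <- build_codon_distribution(usage_regime("uniform", 0.5))
#' nchar(generate_cds(513, dist, seed = 1))  # 1539
#' @export
generate_cds <- function(n_codons, distribution, aa_freq = NULL,
                         gc12_coupling = 0, gc3_target = NULL, seed = NULL) {
  stopifnot(n_codons >= 3)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  fams <- unique(distribution$family)
  if (is.null(aa_freq)) {
    aa_freq <- stats::setNames(rep(1 / length(fams), length(fams)), fams)
  }
  aa_freq <- aa_freq[fams]
  if (gc12_coupling > 0) {
    if (is.null(gc3_target)) {
      stop("gc3_target is required when gc12_coupling > 0", call. = FALSE)
    }
    g <- .family_gc12_load(distribution)[fams]
    g0 <- sum(aa_freq * g / 2) / sum(aa_freq)
    t12 <- g0 + gc12_coupling * (gc3_target - g0)
    p <- .solve_aa_pressure(aa_freq, g, t12)
    aa_freq <- aa_freq * p^g * (1 - p)^(2 - g)
  }
  n_body <- n_codons - 2L
  aa_seq <- sample(fams, n_body, replace = TRUE, prob = aa_freq)
  codons <- character(n_body)
  by_fam <- split(seq_len(n_body), aa_seq)
  for (f in names(by_fam)) {
    rows <- distribution[distribution$family == f, ]
    idx <- by_fam[[f]]
    codons[idx] <- sample(rows$codon, length(idx), replace = TRUE,
                          prob = rows$prob)
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

#' Specify a synthetic CDS cohort
#'
#' Describes a cohort emulating the 18-gene NPV glycoprotein study design:
#' two groups with distinct usage profiles, gene lengths 1500-1593 nt, and
#' per-gene GC3 targets spread evenly over each group's published GC3
#' range (group 1: 48.4-77.5 %, 11 genes; group 2: 51.9-66.7 %, 7 genes).
#' Each group draws one family-skew vector shared by its genes, so groups
#' are separable by their RSCU profiles; per-gene variation comes from the
#' GC3 gradient and multinomial sampling.
#'
#' @param n_genes Number of genes (default 18; group sizes are scaled
#'   proportionally when changed).
#' @param length_range Nucleotide length range (default `c(1500, 1593)`);
#'   realised lengths are multiples of 3.
#' @param regimes Named list of one [usage_regime()] per group; defaults to
#'   two `"selection_dominated"`-style regimes with `gc12_coupling = 0.1`
#'   (the weak mutational contribution typical of this system),
#'   `family_skew = 3`, and the group GC3 ranges above. A single regime
#'   yields a one-group cohort.
#' @param aa_concentration Dirichlet concentration for the cohort-level
#'   amino-acid composition, centred on uniform (default 50).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_genes = 18,
                        length_range = c(1500, 1593),
                        regimes = NULL,
                        aa_concentration = 50) {
  if (is.null(regimes)) {
    regimes <- list(
      group1 = usage_regime("selection_dominated",
                            gc3_target = c(0.484, 0.775),
                            gc12_coupling = 0.1, family_skew = 3),
      group2 = usage_regime("selection_dominated",
                            gc3_target = c(0.519, 0.667),
                            gc12_coupling = 0.1, family_skew = 3)
    )
  }
  if (is.null(names(regimes))) {
    names(regimes) <- paste0("group", seq_along(regimes))
  }
  n_groups <- length(regimes)
  sizes <- if (n_groups == 2L) {
    g1 <- max(1L, min(n_genes - 1L, round(n_genes * 11 / 18)))
    c(g1, n_genes - g1)
  } else {
    base <- rep(n_genes %/% n_groups, n_groups)
    base[seq_len(n_genes %% n_groups)] <- base[seq_len(n_genes %% n_groups)] + 1L
    base
  }
  stopifnot(all(sizes >= 1L), sum(sizes) == n_genes,
            length_range[1] <= length_range[2])
  structure(list(n_genes = n_genes, length_range = length_range,
                 regimes = regimes,
                 group_sizes = stats::setNames(sizes, names(regimes)),
                 aa_concentration = aa_concentration),
            class = "cohort_spec")
}

#' Generate a synthetic CDS cohort with ground truth
#'
#' Realises a [cohort_spec()] under a single seeded RNG stream: draws the
#' cohort amino-acid composition, one family-skew vector per group, then
#' each gene's length, GC3 target (evenly spaced over its group's range)
#' and sequence. The same spec and seed always regenerate byte-identical
#' sequences.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return List with `sequences` (tibble `gene_id`, `group`, `sequence`)
#'   and `manifest` (tibble of per-gene ground truth: group, regime name,
#'   `gc3_target`, `gc12_coupling`, `family_skew`, `length_nt`,
#'   `realized_gc3`, plus the seed).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_genes = 4), seed = 42)
#' cohort$manifest
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  fams <- unique(sense_codons()$family)
  alpha <- spec$aa_concentration
  aa_draw <- stats::rgamma(length(fams), shape = alpha, rate = 1)
  aa_freq <- stats::setNames(aa_draw / sum(aa_draw), fams)

  n_cod_min <- ceiling(spec$length_range[1] / 3)
  n_cod_max <- floor(spec$length_range[2] / 3)

  rows <- list()
  idx <- 0L
  for (gname in names(spec$regimes)) {
    regime <- spec$regimes[[gname]]
    n_g <- spec$group_sizes[[gname]]
    skew <- .draw_family_skew(regime$family_skew)
    targets <- if (length(regime$gc3_target) == 2L) {
      if (n_g == 1L) mean(regime$gc3_target) else
        seq(regime$gc3_target[1], regime$gc3_target[2], length.out = n_g)
    } else {
      rep(regime$gc3_target, n_g)
    }
    for (j in seq_len(n_g)) {
      idx <- idx + 1L
      gene_regime <- regime
      gene_regime$gc3_target <- targets[j]
      dist <- build_codon_distribution(gene_regime, skew = skew)
      n_codons <- sample(seq.int(n_cod_min, n_cod_max), 1L)
      seq_str <- generate_cds(n_codons, dist, aa_freq = aa_freq,
                              gc12_coupling = regime$gc12_coupling,
                              gc3_target = targets[j])
      rows[[idx]] <- tibble::tibble(
        gene_id = sprintf("gene%02d", idx),
        group = gname,
        sequence = seq_str,
        regime_name = regime$name,
        gc3_target = targets[j],
        gc12_coupling = regime$gc12_coupling,
        family_skew = regime$family_skew,
        length_nt = nchar(seq_str)
      )
    }
  }
  all <- dplyr::bind_rows(rows)
  comp <- codon_composition(all[, c("gene_id", "sequence")])
  manifest <- dplyr::bind_cols(
    all[, c("gene_id", "group", "regime_name", "gc3_target",
            "gc12_coupling", "family_skew", "length_nt")],
    realized_gc3 = comp$gc3 / 100
  )
  manifest$seed <- seed
  list(
    sequences = all[, c("gene_id", "group", "sequence")],
    manifest = manifest
  )
}
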