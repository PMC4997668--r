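#' Relative synonymous codon usage
#'
#' RSCU of a codon is its observed count divided by the mean count over its
#' synonymous family, so values average 1 within every family: 1 means the
#' codon is used exactly as often as expected under even synonymous usage,
#' above 1 marks a preferred codon. Computed over the 59 sense codons only
#' (Met, Trp and stops carry no RSCU). A family entirely unused in a gene
#' yields `NA` (undefined), not 0; an unused codon in a used family yields 0.
#'
#' No rounding is applied here; report writers round to 2 decimals
#' (half-up) when mirroring published tables.
#'
#' @param counts Long count tibble from [count_codons()] or [pool_counts()]
#'   (one or more `gene_id` values).
#' @return The 59 sense-codon rows per gene with an added `rscu` column.
#' @examples
#' counts <- tibble::tibble(
#'   gene_id = "pooled",
#'   codon = c("GCU", "GCC", "GCA", "GCG"),
#'   count = c(72L, 168L, 28L, 154L)
#' )
#' rscu(counts)  # GCU -> 0.68 at 2 dp
#' @export
rscu <- function(counts) {
  counts <- .complete_counts(counts)
  sense <- counts[!is.na(counts$family), , drop = FALSE]
  sense |>
    dplyr::group_by(.data$gene_id, .data$family) |>
    dplyr::mutate(
      rscu = if (sum(.data$count) > 0) .data$count / mean(.data$count)
             else NA_real_
    ) |>
    dplyr::ungroup()
}

# accept partial count tables (missing codons treated as 0) and fill in the
# amino-acid/family annotation from the code table
.complete_counts <- function(counts) {
  stopifnot(all(c("codon", "count") %in% names(counts)))
  if (!"gene_id" %in% names(counts)) counts$gene_id <- "gene"
  code <- genetic_code()
  codon_dna <- chartr("U", "T", counts$codon)
  if (!all(codon_dna %in% code$codon)) {
    stop("unknown codon(s): ",
         paste(unique(counts$codon[!codon_dna %in% code$codon]), collapse = ","),
         call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    gene_id = unique(counts$gene_id),
    codon = code$codon_rna
  )
  grid |>
    dplyr::left_join(
      tibble::tibble(gene_id = counts$gene_id,
                     codon = chartr("T", "U", codon_dna),
                     count = counts$count),
      by = c("gene_id", "codon")
    ) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    dplyr::left_join(code[, c("codon_rna", "amino_acid", "family")],
                     by = c(codon = "codon_rna"))
}

#' Wright's effective number of codons (ENC)
#'
#' Quantifies how far a gene departs from even synonymous usage: 20 means
#' one codon per amino acid (maximal bias), 61 means fully even usage. Per
#' synonymous family with \eqn{n \ge 2} codon observations the homozygosity
#' is estimated as \eqn{\hat F = (n \sum \hat p^2 - 1)/(n - 1)}; family
#' estimates are averaged within each degeneracy class and composed as
#' \deqn{ENC = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6,}
#' then capped to \[20, 61\]. Families with fewer than 2 observations or a
#' non-positive \eqn{\hat F} are skipped; an empty degeneracy class takes
#' the mean of the remaining class averages (for the singleton three-fold
#' class, the mean of the two- and four-fold averages).
#'
#' @param counts Long count tibble from [count_codons()] or [pool_counts()].
#' @return Tibble with one row per gene: `gene_id`, `enc`. Genes with no
#'   estimable family get `NA` with a warning.
#' @export
enc <- function(counts) {
  counts <- .complete_counts(counts)
  code <- genetic_code()
  sense <- counts[!is.na(counts$family), , drop = FALSE]
  sense$degeneracy <- code$degeneracy[match(chartr("U", "T", sense$codon),
                                            code$codon)]
  out <- sense |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_map(~ tibble::tibble(gene_id = .y$gene_id,
                                      enc = .enc_one(.x))) |>
    dplyr::bind_rows()
  out[match(unique(sense$gene_id), out$gene_id), ]
}

.enc_one <- function(sense) {
  fam <- split(sense, sense$family)
  f_hat <- vapply(fam, function(f) {
    n <- sum(f$count)
    if (n < 2) return(NA_real_)
    p <- f$count / n
    (n * sum(p^2) - 1) / (n - 1)
  }, numeric(1))
  deg <- vapply(fam, function(f) f$degeneracy[1], numeric(1))
  usable <- !is.na(f_hat) & f_hat > 0
  if (!any(usable)) {
    warning("gene too short to estimate ENC; returning NA", call. = FALSE)
    return(NA_real_)
  }
  class_mean <- vapply(c(2, 3, 4, 6), function(k) {
    v <- f_hat[usable & deg == k]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  names(class_mean) <- c("2", "3", "4", "6")
  # impute empty classes: 3-fold from the 2- and 4-fold means, others from
  # the mean of whatever classes were observed
  if (is.na(class_mean["3"]) && !is.na(class_mean["2"]) &&
      !is.na(class_mean["4"])) {
    class_mean["3"] <- mean(class_mean[c("2", "4")])
  }
  observed <- class_mean[!is.na(class_mean)]
  class_mean[is.na(class_mean)] <- mean(observed)
  value <- 2 + 9 / class_mean["2"] + 1 / class_mean["3"] +
    5 / class_mean["4"] + 3 / class_mean["6"]
  unname(min(61, max(20, value)))
}

#' Relative adaptiveness weights for the codon adaptation index
#'
#' Derives per-codon weights from a reference count table of highly
#' expressed genes: within each synonymous family, `w = count / max(count)`,
#' so the family-optimal codon has weight 1. Reference codons with zero
#' count get a floor of 0.01 (of the family maximum) so that CAI's
#' geometric mean never degenerates to zero.
#'
#' @param reference_counts Count tibble (e.g. from [count_codons()] on a
#'   reference gene set, or [synthetic_cai_reference()]).
#' @param floor Weight assigned to zero-count reference codons
#'   (default 0.01).
#' @return Tibble `codon`, `family`, `w` over the 59 sense codons.
#' @export
cai_weights <- function(reference_counts, floor = 0.01) {
  counts <- .complete_counts(reference_counts)
  if (dplyr::n_distinct(counts$gene_id) > 1L) {
    counts <- pool_counts(counts)
  }
  sense <- counts[!is.na(counts$family), , drop = FALSE]
  empty <- sense |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop") |>
    dplyr::filter(.data$total == 0)
  if (nrow(empty) > 0L) {
    stop("reference set has no observations for family(ies): ",
         paste(empty$family, collapse = ", "), call. = FALSE)
  }
  sense |>
    dplyr::group_by(.data$family) |>
    dplyr::mutate(w = pmax(.data$count / max(.data$count), floor)) |>
    dplyr::ungroup() |>
    dplyr::select("codon", "family", "w")
}

#' Codon adaptation index
#'
#' CAI is the geometric mean, over all sense-codon occurrences in a gene,
#' of each codon's relative adaptiveness against a highly expressed
#' reference set. It ranges over (0, 1]; 1 means the family-optimal codon
#' is always used.
#'
#' @param counts Long count tibble from [count_codons()].
#' @param weights Weight table from [cai_weights()].
#' @return Tibble with one row per gene: `gene_id`, `cai`.
#' @export
cai <- function(counts, weights) {
  counts <- .complete_counts(counts)
  sense <- counts[!is.na(counts$family), , drop = FALSE]
  sense <- dplyr::left_join(sense, weights[, c("codon", "w")], by = "codon")
  missing_w <- sense$count > 0 & is.na(sense$w)
  if (any(missing_w)) {
    stop("no CAI weight for used codon(s): ",
         paste(unique(sense$codon[missing_w]), collapse = ","),
         call. = FALSE)
  }
  sense |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      cai = {
        used <- .data$count > 0
        n <- sum(.data$count[used])
        if (n == 0) stop("gene with no sense codons: cannot compute CAI",
                         call. = FALSE)
        exp(sum(.data$count[used] * log(.data$w[used])) / n)
      },
      .groups = "drop"
    )
}

#' Synthetic highly-expressed reference counts for CAI
#'
#' A deterministic stand-in reference count table emulating a highly
#' expressed, strongly biased gene set: in every synonymous family one
#' codon (the first C-ending codon, else the first G-ending, else the
#' alphabetically first) receives 900 counts and every other codon 100.
#' Real analyses should supply their own reference via [count_codons()];
#' this fixture exists so CAI is computable out of the box.
#'
#' @return A count tibble usable as `reference_counts` in [cai_weights()].
#' @export
synthetic_cai_reference <- function() {
  code <- sense_codons()
  fams <- split(code, code$family)
  rows <- purrr::map(fams, function(f) {
    f <- f[order(f$codon_rna), ]
    pick <- which(endsWith(f$codon_rna, "C"))[1]
    if (is.na(pick)) pick <- which(endsWith(f$codon_rna, "G"))[1]
    if (is.na(pick)) pick <- 1L
    tibble::tibble(codon = f$codon_rna,
                   count = ifelse(seq_len(nrow(f)) == pick, 900L, 100L))
  })
  out <- dplyr::bind_rows(rows)
  out$gene_id <- "synthetic_reference"
  out[, c("gene_id", "codon", "count")]
}

#' Positional nucleotide composition of coding sequences
#'
#' Per-gene GC composition over the analysis codons (leading AUG and
#' terminal stop excluded by default): overall GC, GC1/GC2/GC3 by codon
#' position, GC12 = (GC1 + GC2)/2 (the neutrality-plot ordinate), plus the
#' silent-site third-position composition A3s/T3s/C3s/G3s and GC3s computed
#' over third positions of the 59-codon synonymous universe only (Met, Trp
#' and stop codons excluded). All values are percentages.
#'
#' @param seqs Tibble with `gene_id` and `sequence` columns.
#' @param exclude_start,exclude_stop Passed to the codon splitter
#'   (defaults `TRUE`).
#' @return Tibble with one row per gene: `gene_id`, `length_nt`, `gc`,
#'   `gc1`, `gc2`, `gc3`, `gc12`, `gc3s`, `a3s`, `t3s`, `c3s`, `g3s`.
#' @export
codon_composition <- function(seqs, exclude_start = TRUE,
                              exclude_stop = TRUE) {
  stopifnot(all(c("gene_id", "sequence") %in% names(seqs)))
  code <- genetic_code()
  sense_set <- code$codon[!is.na(code$family)]
  gc_base <- function(x) 100 * mean(x %in% c("G", "C"))
  rows <- purrr::map2(seqs$gene_id, seqs$sequence, function(id, s) {
    cods <- .analysis_codons(s, exclude_start, exclude_stop)
    if (length(cods) == 0L) {
      stop("no analysis codons left in gene ", id, call. = FALSE)
    }
    b1 <- substr(cods, 1, 1); b2 <- substr(cods, 2, 2); b3 <- substr(cods, 3, 3)
    silent3 <- b3[cods %in% sense_set]
    gc1 <- gc_base(b1); gc2 <- gc_base(b2)
    tibble::tibble(
      gene_id = id,
      length_nt = nchar(s),
      gc = gc_base(c(b1, b2, b3)),
      gc1 = gc1, gc2 = gc2, gc3 = gc_base(b3),
      gc12 = (gc1 + gc2) / 2,
      gc3s = gc_base(silent3),
      a3s = 100 * mean(silent3 == "A"),
      t3s = 100 * mean(silent3 == "T"),
      c3s = 100 * mean(silent3 == "C"),
      g3s = 100 * mean(silent3 == "G")
    )
  })
  dplyr::bind_rows(rows)
}

#' Full per-gene codon-usage index table
#'
#' One row per gene with every index the downstream diagnostics consume:
#' length and positional composition from [codon_composition()], ENC from
#' [enc()] and CAI from [cai()]. This is the standard per-gene report
#' column set (A3s...G3s, GC, GC1-GC3, GC3s, ENC, CAI).
#'
#' @param seqs Tibble with `gene_id` and `sequence` columns; extra columns
#'   `species` and `group`, if present, are carried through.
#' @param cai_reference Reference count table for CAI weights; defaults to
#'   [synthetic_cai_reference()].
#' @return A tibble of per-gene index records.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_genes = 4), seed = 1)
#' codon_usage_indices(cohort$sequences)
#' @export
codon_usage_indices <- function(seqs, cai_reference = synthetic_cai_reference()) {
  counts <- count_codons(seqs)
  comp <- codon_composition(seqs)
  enc_tbl <- enc(counts)
  cai_tbl <- cai(counts, cai_weights(cai_reference))
  out <- comp |>
    dplyr::left_join(enc_tbl, by = "gene_id") |>
    dplyr::left_join(cai_tbl, by = "gene_id")
  for (extra in c("species", "group")) {
    if (extra %in% names(seqs)) {
      out[[extra]] <- seqs[[extra]][match(out$gene_id, seqs$gene_id)]
    }
  }
  out
}

# round half-up at d decimals, used only by report writers
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Pooled NPV glycoprotein codon counts
#'
#' The published pooled codon-usage table for the envelope glycoprotein
#' genes of 18 nuclear polyhedrosis virus species (9,236 codons in total;
#' 8,709 over the 59 sense codons), shipped with the package as a plain-text
#' fixture. Columns: `amino_acid`, `codon` (RNA), `count` and
#' `rscu_published` (the published 2-decimal RSCU, for cross-checking).
#'
#' @return A 59-row tibble.
#' @examples
#' tab <- npv_glycoprotein_counts()
#' sum(tab$count)
#' @export
npv_glycoprotein_counts <- function() {
  path <- system.file("extdata", "npv_glycoprotein_pooled_codons.tsv",
                      package = "codonuse", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    amino_acid = readr::col_character(),
    codon = readr::col_character(),
    count = readr::col_integer(),
    rscu_published = readr::col_double()
  ))
}
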