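#' Read coding sequences from a FASTA file
#'
#' Reads a multi-record FASTA of in-frame CDS. Lowercase input is folded to
#' uppercase and U is normalised to T, so sequences are held internally in
#' the DNA alphabet (reports use RNA codons).
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @return A tibble with one row per record, in file order: `gene_id` (the
#'   first whitespace-delimited token of the header), `description` (the full
#'   header) and `sequence` (uppercase DNA).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1 demo", "ATGAAATTTTAA"), fa)
#' read_cds_fasta(fa)
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) {
    stop("FASTA file contains no records: ", path, call. = FALSE)
  }
  seqs <- toupper(as.character(recs))
  seqs <- chartr("U", "T", seqs)
  headers <- names(recs)
  tibble::tibble(
    gene_id = vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L),
    description = headers,
    sequence = unname(seqs)
  )
}

#' Write coding sequences to a FASTA file
#'
#' @param seqs A tibble with columns `gene_id` and `sequence` (as returned by
#'   [read_cds_fasta()] or [generate_cohort()]).
#' @param path Output path.
#' @param width Line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(seqs, path, width = 70L) {
  stopifnot(all(c("gene_id", "sequence") %in% names(seqs)))
  x <- Biostrings::BStringSet(seqs$sequence)
  names(x) <- seqs$gene_id
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Validate coding sequences
#'
#' Checks each CDS against frame and alphabet rules: length must be a
#' multiple of 3, the alphabet is restricted to A/C/G/T (plus N up to
#' `max_n_frac`), and internal stop codons are flagged. Under the default
#' policy internal stops produce a warning but do not reject the sequence
#' (they are counted as stops downstream and excluded from sense-codon
#' analyses).
#'
#' @param seqs Tibble with `gene_id` and `sequence` columns.
#' @param max_n_frac Maximum tolerated fraction of N bases (default 0.05).
#' @param internal_stop `"warn"` (default), `"reject"` or `"ignore"`.
#' @return The accepted rows of `seqs` (same columns). Rejected rows are
#'   attached as `attr(, "rejections")`, a tibble with `gene_id` and
#'   `reason`.
#' @examples
#' seqs <- tibble::tibble(gene_id = c("ok", "bad"),
#'                        sequence = c("ATGAAATAA", "ATGAAAT"))
#' ok <- validate_cds(seqs)
#' attr(ok, "rejections")
#' @export
validate_cds <- function(seqs, max_n_frac = 0.05,
                         internal_stop = c("warn", "reject", "ignore")) {
  internal_stop <- match.arg(internal_stop)
  stopifnot(all(c("gene_id", "sequence") %in% names(seqs)))
  code <- genetic_code()
  stops <- code$codon[code$aa == "*"]

  reason <- rep(NA_character_, nrow(seqs))
  for (i in seq_len(nrow(seqs))) {
    s <- seqs$sequence[[i]]
    n <- nchar(s)
    if (n == 0L) {
      reason[i] <- "empty sequence"
      next
    }
    if (n %% 3L != 0L) {
      reason[i] <- "length not multiple of 3"
      next
    }
    bases <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(bases), c("A", "C", "G", "T", "N"))
    if (length(bad) > 0L) {
      reason[i] <- paste0("invalid characters: ", paste(bad, collapse = ","))
      next
    }
    if (sum(bases == "N") / n > max_n_frac) {
      reason[i] <- sprintf("N content exceeds %.0f%%", 100 * max_n_frac)
      next
    }
    if (internal_stop != "ignore") {
      cods <- .split_codons(s)
      internal <- cods[-length(cods)] %in% stops
      if (any(internal)) {
        msg <- sprintf("%s: internal stop codon at codon %s",
                       seqs$gene_id[[i]],
                       paste(which(internal), collapse = ","))
        if (internal_stop == "reject") {
          reason[i] <- "internal stop codon"
        } else {
          warning(msg, call. = FALSE)
        }
      }
    }
  }

  keep <- is.na(reason)
  out <- seqs[keep, , drop = FALSE]
  attr(out, "rejections") <- tibble::tibble(
    gene_id = seqs$gene_id[!keep],
    reason = reason[!keep]
  )
  out
}

# split a DNA string into in-frame triplets
.split_codons <- function(sequence) {
  n <- nchar(sequence)
  stopifnot(n %% 3L == 0L)
  starts <- seq.int(1L, n, by = 3L)
  substring(sequence, starts, starts + 2L)
}

# analysis codons for one gene: in-frame triplets minus the leading ATG /
# terminal stop (when requested) and minus N-containing triplets
.analysis_codons <- function(sequence, exclude_start = TRUE,
                             exclude_stop = TRUE) {
  code <- genetic_code()
  stops <- code$codon[code$aa == "*"]
  cods <- .split_codons(sequence)
  if (exclude_start && length(cods) > 0L && cods[1L] == "ATG") {
    cods <- cods[-1L]
  }
  if (exclude_stop && length(cods) > 0L && cods[length(cods)] %in% stops) {
    cods <- cods[-length(cods)]
  }
  dropped <- grepl("N", cods, fixed = TRUE)
  if (any(dropped)) {
    message(sum(dropped), " codon(s) containing N dropped from counts")
  }
  cods[!dropped]
}

#' Count codons per gene
#'
#' Tabulates in-frame codon usage for each sequence. By default the leading
#' AUG and the terminal stop codon are excluded, matching the 59-sense-codon
#' universe used by all downstream indices. Codons containing N are dropped
#' (never imputed) and a message reports how many.
#'
#' @param seqs Tibble with `gene_id` and `sequence` columns (validated CDS).
#' @param exclude_start,exclude_stop Drop the leading AUG / terminal stop
#'   codon before counting (defaults `TRUE`).
#' @return A tibble in long form with one row per gene and codon (64 rows
#'   per gene): `gene_id`, `codon` (RNA spelling), `amino_acid`, `family`,
#'   `count`.
#' @examples
#' seqs <- tibble::tibble(gene_id = "g", sequence = "ATGAAAAAATAA")
#' counts <- count_codons(seqs)
#' counts[counts$count > 0, ]
#' @export
count_codons <- function(seqs, exclude_start = TRUE, exclude_stop = TRUE) {
  stopifnot(all(c("gene_id", "sequence") %in% names(seqs)))
  code <- genetic_code()
  per_gene <- purrr::map2(seqs$gene_id, seqs$sequence, function(id, s) {
    cods <- .analysis_codons(s, exclude_start, exclude_stop)
    cnt <- table(factor(cods, levels = code$codon))
    tibble::tibble(
      gene_id = id,
      codon = code$codon_rna,
      amino_acid = code$amino_acid,
      family = code$family,
      count = as.integer(cnt)
    )
  })
  dplyr::bind_rows(per_gene)
}

#' Pool codon count tables
#'
#' Adds codon counts entrywise across genes (or across already-pooled
#' tables), producing one 64-row table. `gene_id` becomes the concatenation
#' of the contributing ids.
#'
#' @param counts A long count tibble from [count_codons()] (any number of
#'   `gene_id` values), or a list of such tibbles.
#' @return A one-table tibble with columns `gene_id`, `codon`,
#'   `amino_acid`, `family`, `count`.
#' @export
pool_counts <- function(counts) {
  if (is.data.frame(counts)) counts <- list(counts)
  if (length(counts) == 0L) {
    stop("pool_counts() needs at least one count table", call. = FALSE)
  }
  all <- dplyr::bind_rows(lapply(counts, function(x) {
    .complete_counts(x[, intersect(names(x), c("gene_id", "codon", "count"))])
  }))
  ids <- unique(all$gene_id)
  pooled <- all |>
    dplyr::group_by(.data$codon, .data$amino_acid, .data$family) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  code <- genetic_code()
  pooled <- pooled[match(code$codon_rna, pooled$codon), ]
  tibble::tibble(
    gene_id = paste(ids, collapse = "+"),
    pooled[, c("codon", "amino_acid", "family", "count")]
  )
}
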