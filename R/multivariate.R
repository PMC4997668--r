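#' Spread a long RSCU table to a genes-by-codon matrix
#'
#' @param rscu_tbl Long tibble from [rscu()] (`gene_id`, `codon`, `rscu`).
#' @param impute_undefined Value used for undefined RSCU entries (families
#'   unused in a gene); default 0, with a message when any are imputed.
#' @return A numeric matrix, genes in rows (named), the 59 sense codons in
#'   columns.
#' @export
rscu_wide <- function(rscu_tbl, impute_undefined = 0) {
  stopifnot(all(c("gene_id", "codon", "rscu") %in% names(rscu_tbl)))
  n_na <- sum(is.na(rscu_tbl$rscu))
  if (n_na > 0L) {
    message(n_na, " undefined RSCU entr(ies) imputed as ", impute_undefined)
  }
  wide <- rscu_tbl |>
    dplyr::mutate(rscu = dplyr::coalesce(.data$rscu, impute_undefined)) |>
    tidyr::pivot_wider(id_cols = "gene_id", names_from = "codon",
                       values_from = "rscu")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$gene_id
  m
}

#' Correspondence analysis of an RSCU matrix
#'
#' Classical (chi-square metric) correspondence analysis of the
#' genes-by-codon RSCU table: the matrix is normalised to a correspondence
#' table, the standardised residuals
#' \eqn{S = D_r^{-1/2}(P - r c^\top) D_c^{-1/2}} are decomposed by SVD, and
#' genes (rows) and codons (columns) are reported in principal coordinates.
#' Each axis carries a fraction of the total inertia equal to its squared
#' singular value over the sum. Axis signs are fixed so that the codon with
#' the largest absolute coordinate on each axis is positive, making outputs
#' deterministic.
#'
#' @param x Either a long RSCU tibble (from [rscu()]) or a non-negative
#'   genes-by-codon matrix.
#' @param n_axes Maximum number of axes to report (default 10, truncated to
#'   the rank).
#' @return An object of class `rscu_ca` with elements `inertia` (tibble:
#'   `axis`, `inertia`, `fraction`, `cumulative`), `genes` (tibble of
#'   principal coordinates `axis1..axisK`), `codons` (idem, plus
#'   `ending_base` and `ending_class`, G/C- vs A/U-ending third base) and
#'   `total_inertia`. With no variation at all (identical row profiles) the
#'   coordinate tables have zero axis columns and `total_inertia` is 0.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_genes = 6), seed = 1)
#' ca <- rscu_ca(rscu(count_codons(cohort$sequences)))
#' tidy(ca, "inertia")
#' @export
rscu_ca <- function(x, n_axes = 10) {
  if (is.data.frame(x)) x <- rscu_wide(x)
  if (any(x < 0)) stop("input matrix must be non-negative", call. = FALSE)
  zero_col <- colSums(x) == 0
  if (any(zero_col)) {
    message(sum(zero_col), " all-zero codon column(s) dropped from the CA")
    x <- x[, !zero_col, drop = FALSE]
  }
  if (any(rowSums(x) == 0)) {
    stop("all-zero gene row(s): ",
         paste(rownames(x)[rowSums(x) == 0], collapse = ","), call. = FALSE)
  }

  p <- x / sum(x)
  r <- rowSums(p)
  c <- colSums(p)
  s <- diag(1 / sqrt(r)) %*% (p - outer(r, c)) %*% diag(1 / sqrt(c))
  sv <- svd(s)
  keep <- sv$d > max(sv$d[1], .Machine$double.eps) * 1e-8
  d <- sv$d[keep]
  total <- sum(d^2)

  code <- genetic_code()
  third <- code$third_base[match(chartr("U", "T", colnames(x)), code$codon)]
  codon_base <- tibble::tibble(
    codon = colnames(x),
    ending_base = third,
    ending_class = ifelse(third %in% c("G", "C"), "G/C", "A/U")
  )

  if (total < .Machine$double.eps) {
    out <- list(
      inertia = tibble::tibble(axis = integer(), inertia = numeric(),
                               fraction = numeric(), cumulative = numeric()),
      genes = tibble::tibble(gene_id = rownames(x)),
      codons = codon_base,
      total_inertia = 0
    )
    return(structure(out, class = "rscu_ca"))
  }

  k <- min(n_axes, length(d))
  d <- d[seq_len(k)]
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  frow <- sweep(u, 1, sqrt(r), "/") %*% diag(d, k)
  fcol <- sweep(v, 1, sqrt(c), "/") %*% diag(d, k)
  # deterministic axis orientation: largest-|coordinate| codon positive
  for (a in seq_len(k)) {
    flip <- sign(fcol[which.max(abs(fcol[, a])), a])
    if (flip < 0) {
      fcol[, a] <- -fcol[, a]
      frow[, a] <- -frow[, a]
    }
  }
  axes <- paste0("axis", seq_len(k))
  colnames(frow) <- colnames(fcol) <- axes

  all_d <- sv$d[keep]
  inertia <- tibble::tibble(
    axis = seq_along(all_d),
    inertia = all_d^2,
    fraction = all_d^2 / total
  )
  inertia$cumulative <- cumsum(inertia$fraction)

  structure(list(
    inertia = inertia,
    genes = tibble::tibble(gene_id = rownames(x),
                           tibble::as_tibble(frow)),
    codons = tibble::tibble(codon_base, tibble::as_tibble(fcol)),
    total_inertia = total,
    row_mass = r
  ), class = "rscu_ca")
}

#' @export
print.rscu_ca <- function(x, ...) {
  cat("Correspondence analysis of RSCU:",
      nrow(x$genes), "genes x", nrow(x$codons), "codons\n")
  cat("Total inertia:", format(x$total_inertia, digits = 4), "\n")
  if (nrow(x$inertia) > 0) {
    top <- utils::head(x$inertia, 2)
    cat(sprintf("Axis %d: %.2f%%\n", top$axis, 100 * top$fraction), sep = "")
  }
  invisible(x)
}

#' Tidy a correspondence analysis
#'
#' @param x An `rscu_ca` object.
#' @param type One of `"inertia"`, `"genes"`, `"codons"`.
#' @param ... Unused.
#' @return The requested component as a tibble.
#' @method tidy rscu_ca
#' @export
tidy.rscu_ca <- function(x, type = c("inertia", "genes", "codons"), ...) {
  type <- match.arg(type)
  x[[type]]
}

#' @method autoplot rscu_ca
#' @export
autoplot.rscu_ca <- function(object, type = c("genes", "codons"), ...) {
  type <- match.arg(type)
  d <- object[[type]]
  if (!all(c("axis1", "axis2") %in% names(d))) {
    stop("fewer than 2 axes available", call. = FALSE)
  }
  lab <- sprintf("Axis %d (%.1f%%)", 1:2, 100 * object$inertia$fraction[1:2])
  if (type == "codons") {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$axis1, y = .data$axis2,
                                    colour = .data$ending_class)) +
      ggplot2::geom_point() +
      ggplot2::labs(x = lab[1], y = lab[2], colour = "Third base")
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$axis1, y = .data$axis2)) +
      ggplot2::geom_point() +
      ggplot2::labs(x = lab[1], y = lab[2])
  }
}

#' Summarise codon coordinates by third-base class
#'
#' Compares G/C-ending and A/U-ending codons in the correspondence plane:
#' mean absolute displacement from Axis 1 (i.e. |Axis 2|), the spread along
#' Axis 1, and which class lies closer to Axis 1.
#'
#' @param ca An `rscu_ca` object with at least 2 axes.
#' @return A 2-row tibble (`ending_class`, `n_codons`, `mean_axis1`,
#'   `sd_axis1`, `mean_abs_axis2`, `closer_to_axis1`).
#' @export
codon_ending_summary <- function(ca) {
  d <- ca$codons
  if (!all(c("axis1", "axis2") %in% names(d))) {
    stop("correspondence result has fewer than 2 axes", call. = FALSE)
  }
  out <- d |>
    dplyr::group_by(.data$ending_class) |>
    dplyr::summarise(
      n_codons = dplyr::n(),
      mean_axis1 = mean(.data$axis1),
      sd_axis1 = stats::sd(.data$axis1),
      mean_abs_axis2 = mean(abs(.data$axis2)),
      .groups = "drop"
    )
  if (diff(range(out$mean_abs_axis2)) < .Machine$double.eps) {
    out$closer_to_axis1 <- "tie"
  } else {
    out$closer_to_axis1 <- ifelse(
      out$mean_abs_axis2 == min(out$mean_abs_axis2), "yes", "no")
  }
  out
}
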