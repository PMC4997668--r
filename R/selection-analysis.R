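#' Expected ENC under pure mutational pressure
#'
#' Wright's standard curve for the ENC plot: the ENC a gene would show if
#' codon usage were driven solely by third-position base composition,
#' \deqn{ENC^* = 2 + s + 29 / (s^2 + (1 - s)^2)}
#' with \eqn{s} the silent-site GC content (GC3s) as a fraction.
#'
#' @param gc3s Numeric vector of GC3s fractions, strictly inside (0, 1).
#' @return Expected ENC values.
#' @examples
#' enc_expected(0.5)  # 60.5, the maximum of the curve
#' @export
enc_expected <- function(gc3s) {
  if (any(gc3s <= 0 | gc3s >= 1)) {
    stop("gc3s must lie strictly inside (0, 1)", call. = FALSE)
  }
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' ENC-plot points against the mutational-pressure curve
#'
#' For each gene, compares observed ENC with the ENC expected from its
#' GC3s under pure mutational pressure. Genes on or near the curve are
#' consistent with mutation pressure as the driver of their bias; genes
#' well below it implicate selection or other forces.
#'
#' @param records Per-gene index tibble from [codon_usage_indices()]
#'   (needs `gene_id`, `gc3s` in percent, `enc`; `group` carried if
#'   present).
#' @param tolerance Half-width, in ENC units, of the "on the curve" band
#'   (default 1).
#' @return Tibble `gene_id`, (`group`,) `gc3s`, `enc_observed`,
#'   `enc_expected`, `deviation` (expected minus observed) and `position`
#'   (`"on"`, `"above"` or `"below"`). A named count of the three classes
#'   is attached as `attr(, "summary")`.
#' @export
enc_plot_points <- function(records, tolerance = 1) {
  stopifnot(all(c("gene_id", "gc3s", "enc") %in% names(records)))
  records <- records[!is.na(records$enc), , drop = FALSE]
  if (nrow(records) == 0L) stop("no genes with a defined ENC", call. = FALSE)
  out <- tibble::tibble(
    gene_id = records$gene_id,
    gc3s = records$gc3s,
    enc_observed = records$enc,
    enc_expected = enc_expected(records$gc3s / 100)
  )
  if ("group" %in% names(records)) {
    out <- dplyr::mutate(out, group = records$group, .after = "gene_id")
  }
  out$deviation <- out$enc_expected - out$enc_observed
  out$position <- dplyr::case_when(
    abs(out$deviation) <= tolerance ~ "on",
    out$deviation > 0 ~ "below",
    TRUE ~ "above"
  )
  attr(out, "summary") <- c(
    on = sum(out$position == "on"),
    below = sum(out$position == "below"),
    above = sum(out$position == "above")
  )
  out
}

#' Plot ENC against GC3s with the mutational-pressure curve
#'
#' @param points Tibble from [enc_plot_points()].
#' @return A ggplot object.
#' @export
plot_enc_curve <- function(points) {
  curve <- tibble::tibble(gc3s = seq(1, 99, by = 0.5))
  curve$enc <- enc_expected(curve$gc3s / 100)
  aes_pts <- if ("group" %in% names(points)) {
    ggplot2::aes(x = .data$gc3s, y = .data$enc_observed,
                 colour = .data$group)
  } else {
    ggplot2::aes(x = .data$gc3s, y = .data$enc_observed)
  }
  ggplot2::ggplot() +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$gc3s, y = .data$enc),
                       colour = "darkgreen") +
    ggplot2::geom_point(data = points, aes_pts) +
    ggplot2::labs(x = "GC3s (%)", y = "ENC") +
    ggplot2::coord_cartesian(ylim = c(20, 62))
}

#' Neutrality-plot regression of GC12 on GC3
#'
#' Ordinary least squares of GC12 (mean GC at codon positions 1 and 2) on
#' GC3, fitted for the full cohort and, when a grouping is available, for
#' each group. The slope is read as the fraction of the bias attributable
#' to directional mutation pressure: a slope of 1 (the diagonal) means
#' mutation pressure alone; `mutation_pct = 100 * slope` and
#' `selection_pct = 100 * (1 - slope)` always sum to 100.
#'
#' @param records Per-gene index tibble (needs `gc12`, `gc3`, both in
#'   percent; optional `group`).
#' @param group Optional character vector of group labels overriding the
#'   `group` column.
#' @return An object of class `neutrality_fit`. Use [generics::tidy()] for
#'   the per-group coefficient table, [generics::glance()] for the pooled
#'   fit, and [ggplot2::autoplot()] for the plot.
#' @export
neutrality_fit <- function(records, group = NULL) {
  stopifnot(all(c("gc12", "gc3") %in% names(records)))
  if (is.null(group) && "group" %in% names(records)) group <- records$group
  data <- tibble::tibble(gene_id = records$gene_id,
                         gc3 = records$gc3, gc12 = records$gc12,
                         group = if (is.null(group)) NA_character_
                                 else as.character(group))
  sets <- list(all = data)
  if (!all(is.na(data$group))) {
    sets <- c(sets, split(data, data$group))
  }
  fits <- list()
  for (nm in names(sets)) {
    d <- sets[[nm]]
    problem <- if (nrow(d) < 3L) {
      "has fewer than 3 genes"
    } else if (stats::var(d$gc3) < .Machine$double.eps) {
      "has no GC3 variance; fit is degenerate"
    }
    if (!is.null(problem)) {
      # the pooled fit must exist; undersized groups are merely skipped
      if (nm == "all") stop("group 'all' ", problem, call. = FALSE)
      warning("group '", nm, "' ", problem, "; skipped", call. = FALSE)
      next
    }
    fits[[nm]] <- stats::lm(gc12 ~ gc3, data = d)
  }
  structure(list(fits = fits, data = data), class = "neutrality_fit")
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat("Neutrality-plot regression (GC12 ~ GC3)\n")
  print(generics::tidy(x), ...)
  invisible(x)
}

#' Tidy a neutrality fit
#'
#' @param x A `neutrality_fit` object.
#' @param ... Unused.
#' @return One row per fitted set (`all` plus each group): `group`,
#'   `n_genes`, `slope`, `intercept`, `r_squared`, `mutation_pct`,
#'   `selection_pct`.
#' @method tidy neutrality_fit
#' @export
tidy.neutrality_fit <- function(x, ...) {
  purrr::imap(x$fits, function(fit, nm) {
    cf <- stats::coef(fit)
    # R^2 from the residuals directly; summary.lm warns on perfect fits
    y <- stats::model.frame(fit)$gc12
    r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
    tibble::tibble(
      group = nm,
      n_genes = stats::nobs(fit),
      slope = unname(cf["gc3"]),
      intercept = unname(cf["(Intercept)"]),
      r_squared = r2,
      mutation_pct = 100 * unname(cf["gc3"]),
      selection_pct = 100 * (1 - unname(cf["gc3"]))
    )
  }) |>
    dplyr::bind_rows()
}

#' Glance at a neutrality fit
#'
#' @param x A `neutrality_fit` object.
#' @param ... Unused.
#' @return The one-row summary of the pooled (all-genes) regression.
#' @method glance neutrality_fit
#' @export
glance.neutrality_fit <- function(x, ...) {
  tidy.neutrality_fit(x)[1, ]
}

#' @method autoplot neutrality_fit
#' @export
autoplot.neutrality_fit <- function(object, ...) {
  d <- object$data
  has_groups <- !all(is.na(d$group))
  aes_pts <- if (has_groups) {
    ggplot2::aes(x = .data$gc3, y = .data$gc12, colour = .data$group)
  } else {
    ggplot2::aes(x = .data$gc3, y = .data$gc12)
  }
  p <- ggplot2::ggplot(d, aes_pts) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "red") +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "GC3 (%)", y = "GC12 (%)")
  p
}

#' Pearson correlation table across codon-usage indices
#'
#' Pairwise Pearson correlations (with two-sided t-based p-values) among
#' the per-gene indices and, when supplied, the first two correspondence
#' axes — the standard companion table to a correspondence analysis of
#' RSCU. Significance stars: `*` at p < 0.05, `**` at p < 0.01.
#'
#' @param records Per-gene index tibble from [codon_usage_indices()].
#' @param axes Optional tibble of per-gene axis coordinates (`gene_id`,
#'   `axis1`, `axis2`), e.g. `tidy(ca, "genes")` from [rscu_ca()].
#' @param variables Character vector of columns to correlate; defaults to
#'   the standard column set present in `records`.
#' @return An object of class `usage_correlation` holding matrices `r` and
#'   `p`; `tidy()` returns the long lower-triangle table with stars.
#' @export
correlation_table <- function(records, axes = NULL, variables = NULL) {
  data <- records
  if (!is.null(axes)) {
    stopifnot(all(c("gene_id", "axis1", "axis2") %in% names(axes)))
    data <- dplyr::left_join(data, axes[, c("gene_id", "axis1", "axis2")],
                             by = "gene_id")
  }
  if (is.null(variables)) {
    variables <- intersect(
      c("length_nt", "gc", "gc1", "gc2", "gc3", "gc3s",
        "a3s", "t3s", "c3s", "g3s", "enc", "cai", "axis1", "axis2"),
      names(data)
    )
  }
  if (nrow(data) < 3L) stop("need at least 3 genes", call. = FALSE)
  m <- as.matrix(data[, variables])
  k <- length(variables)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      xi <- m[, i]; xj <- m[, j]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next  # flagged as NA
      ct <- stats::cor.test(xi, xj, method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, n = nrow(data)),
            class = "usage_correlation")
}

#' @export
print.usage_correlation <- function(x, ...) {
  cat("Pearson correlations over", x$n, "genes\n")
  print(generics::tidy(x), ...)
  invisible(x)
}

#' Tidy a correlation table
#'
#' @param x A `usage_correlation` object.
#' @param ... Unused.
#' @return Long tibble of the lower triangle: `var1`, `var2`, `r`, `p`,
#'   `stars` (`""`, `"*"` or `"**"`).
#' @method tidy usage_correlation
#' @export
tidy.usage_correlation <- function(x, ...) {
  vars <- rownames(x$r)
  idx <- which(lower.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    var1 = vars[idx[, "row"]],
    var2 = vars[idx[, "col"]],
    r = x$r[idx],
    p = x$p[idx],
    stars = dplyr::case_when(
      is.na(x$p[idx]) ~ NA_character_,
      x$p[idx] < 0.01 ~ "**",
      x$p[idx] < 0.05 ~ "*",
      TRUE ~ ""
    )
  )
}
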