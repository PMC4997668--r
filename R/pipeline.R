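#' Reproduce the pooled RSCU report from a codon count table
#'
#' Computes RSCU from a pooled count table and formats the published-style
#' report: counts, RSCU rounded half-up to 2 decimals, and preferred-codon
#' flags (`preferred` at RSCU > 1.0 strictly, `strong` at RSCU > 1.5). By
#' default it runs on the packaged pooled NPV glycoprotein counts
#' ([npv_glycoprotein_counts()]).
#'
#' @param counts Count tibble (`codon`, `count`); defaults to the packaged
#'   pooled table.
#' @return Tibble `amino_acid`, `codon`, `count`, `rscu` (unrounded),
#'   `rscu_2dp`, `preferred`, `strong`.
#' @examples
#' tab <- reproduce_pooled_rscu()
#' sum(tab$preferred)  # 24 of 59 codons
#' @export
reproduce_pooled_rscu <- function(counts = npv_glycoprotein_counts()) {
  r <- rscu(counts)
  r <- r[!is.na(r$rscu), ]
  tibble::tibble(
    amino_acid = r$amino_acid,
    codon = r$codon,
    count = r$count,
    rscu = r$rscu,
    rscu_2dp = round_half_up(r$rscu, 2),
    preferred = r$rscu > 1.0,
    strong = r$rscu > 1.5
  )
}

#' Run the full codon-usage analysis pipeline
#'
#' Orchestrates every stage of the analysis on a cohort of CDS — indices,
#' RSCU tables, ENC plot, neutrality regression, correspondence analysis,
#' correlation table, RSCU distances, cluster and NJ trees, and the k-group
#' partition — and writes all report files to `out_dir`. The run is a pure
#' function of (input, configuration, seed): two runs with the same
#' arguments produce byte-identical bundles. On any stage failure the
#' partially written bundle is removed.
#'
#' Report files written (all TSV except the trees):
#' `indices.tsv` (per-gene index table plus `mean`/`sd` rows),
#' `rscu_per_gene.tsv`, `rscu_pooled.tsv` (with preferred-codon flags),
#' `enc_plot.tsv`, `neutrality.tsv`, `ca_inertia.tsv`,
#' `ca_gene_coordinates.tsv`, `ca_codon_coordinates.tsv`,
#' `correlations.tsv`, `rscu_distance.tsv`, `cluster_tree.nwk`,
#' `nj_tree.nwk`, `partition.tsv`, `run_manifest.txt`, `run_log.txt`.
#'
#' @param input A FASTA path, a sequence tibble (`gene_id`, `sequence`,
#'   optional `group`), or a [cohort_spec()] (realised with `seed`).
#' @param out_dir Output directory (created if missing).
#' @param cai_reference Reference counts for CAI weights; default the
#'   synthetic built-in ([synthetic_cai_reference()]).
#' @param grouping `"auto"` (default: the k-group cluster cut labels the
#'   genes for the stratified analyses, unless the input carries a `group`
#'   column) or a tibble (`gene_id`, `group`).
#' @param linkage,k Clustering options, see [usage_cluster()].
#' @param seed Integer seed used for any synthetic input.
#' @return Invisibly, a list with the computed tables and trees.
#' @export
run_pipeline <- function(input, out_dir,
                         cai_reference = synthetic_cai_reference(),
                         grouping = "auto", linkage = "average", k = 2,
                         seed = 1) {
  stage <- "setup"
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  staging <- file.path(tempfile("codonuse_run"))
  dir.create(staging, recursive = TRUE)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)

  result <- tryCatch({
    stage <- "input"
    if (inherits(input, "cohort_spec")) {
      cohort <- generate_cohort(input, seed = seed)
      seqs <- cohort$sequences
      note("input: synthetic cohort of ", nrow(seqs), " genes (seed ", seed, ")")
    } else if (is.character(input) && length(input) == 1L) {
      seqs <- read_cds_fasta(input)
      note("input: FASTA ", input, " (", nrow(seqs), " records)")
    } else if (is.data.frame(input)) {
      seqs <- input
      note("input: in-memory table of ", nrow(seqs), " sequences")
    } else {
      stop("input must be a FASTA path, a sequence tibble or a cohort_spec")
    }

    stage <- "validation"
    seqs <- validate_cds(seqs)
    rej <- attr(seqs, "rejections")
    if (nrow(rej) > 0L) {
      note("rejected ", nrow(rej), " sequence(s): ",
           paste(rej$gene_id, rej$reason, sep = ": ", collapse = "; "))
    }
    if (nrow(seqs) < 3L) stop("fewer than 3 valid sequences")

    stage <- "counting"
    counts <- count_codons(seqs)
    pooled <- pool_counts(counts)

    stage <- "indices"
    records <- codon_usage_indices(seqs, cai_reference = cai_reference)

    stage <- "rscu"
    rscu_gene <- rscu(counts)
    rscu_pooled <- reproduce_pooled_rscu(pooled)

    stage <- "clustering"
    dmat <- rscu_distance(rscu_gene)
    clust <- usage_cluster(dmat, linkage = linkage, k = k)
    njt <- neighbor_joining(dmat)

    stage <- "grouping"
    if (is.data.frame(grouping)) {
      records$group <- grouping$group[match(records$gene_id, grouping$gene_id)]
      note("grouping: user-supplied table")
    } else if ("group" %in% names(seqs)) {
      records$group <- seqs$group[match(records$gene_id, seqs$gene_id)]
      note("grouping: input group labels")
    } else {
      records$group <- paste0("cluster", clust$partition$cluster[
        match(records$gene_id, clust$partition$gene_id)])
      note("grouping: automatic k=", k, " cluster cut")
    }

    stage <- "enc_plot"
    encp <- enc_plot_points(records)

    stage <- "neutrality"
    nfit <- neutrality_fit(records)

    stage <- "correspondence"
    ca <- rscu_ca(rscu_gene)
    axes <- ca$genes[, c("gene_id", "axis1", "axis2")]

    stage <- "correlation"
    cors <- correlation_table(records, axes = axes)

    stage <- "writing"
    w <- function(x, file) readr::write_tsv(x, file.path(staging, file))

    idx_report <- records |>
      dplyr::select("gene_id", "group", "length_nt", "gc", "gc1", "gc2",
                    "gc3", "gc12", "gc3s", "a3s", "t3s", "c3s", "g3s",
                    "enc", "cai")
    num_cols <- names(idx_report)[vapply(idx_report, is.numeric, logical(1))]
    summary_rows <- dplyr::bind_rows(
      c(gene_id = "mean", group = NA,
        lapply(idx_report[num_cols], mean)),
      c(gene_id = "sd", group = NA,
        lapply(idx_report[num_cols], stats::sd))
    )
    idx_out <- dplyr::bind_rows(idx_report, summary_rows)
    idx_out[num_cols] <- lapply(idx_out[num_cols], round_half_up, digits = 2)
    w(idx_out, "indices.tsv")

    rscu_gene_out <- rscu_gene |>
      dplyr::mutate(rscu = round_half_up(.data$rscu, 2)) |>
      dplyr::select("gene_id", "amino_acid", "codon", "count", "rscu")
    w(rscu_gene_out, "rscu_per_gene.tsv")
    w(dplyr::mutate(rscu_pooled, rscu = NULL), "rscu_pooled.tsv")

    encp_out <- dplyr::mutate(
      encp, dplyr::across(dplyr::where(is.numeric), \(x) round_half_up(x, 2)))
    w(encp_out, "enc_plot.tsv")

    w(dplyr::mutate(tidy(nfit),
                    dplyr::across(dplyr::where(is.numeric), \(x) round(x, 4))),
      "neutrality.tsv")

    w(dplyr::mutate(ca$inertia,
                    dplyr::across(dplyr::where(is.numeric), \(x) round(x, 6))),
      "ca_inertia.tsv")
    w(dplyr::mutate(ca$genes,
                    dplyr::across(dplyr::where(is.numeric), \(x) round(x, 6))),
      "ca_gene_coordinates.tsv")
    w(dplyr::mutate(ca$codons,
                    dplyr::across(dplyr::where(is.numeric), \(x) round(x, 6))),
      "ca_codon_coordinates.tsv")

    w(tidy(cors), "correlations.tsv")

    dm <- as.matrix(dmat)
    dm_tbl <- tibble::tibble(gene_id = rownames(dm),
                             tibble::as_tibble(round(dm, 6)))
    w(dm_tbl, "rscu_distance.tsv")

    write_newick(clust, file.path(staging, "cluster_tree.nwk"))
    write_newick(njt, file.path(staging, "nj_tree.nwk"))
    w(clust$partition, "partition.tsv")

    stage <- "manifest"
    manifest <- c(
      paste0("package: codonuse ",
             as.character(utils::packageVersion("codonuse"))),
      paste0("seed: ", seed),
      paste0("n_genes: ", nrow(seqs)),
      paste0("linkage: ", linkage),
      paste0("k: ", k)
    )
    writeLines(manifest, file.path(staging, "run_manifest.txt"))
    note("pipeline complete: ", nrow(seqs), " genes")
    writeLines(log_lines, file.path(staging, "run_log.txt"))

    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (f in list.files(staging)) {
      file.copy(file.path(staging, f), file.path(out_dir, f),
                overwrite = TRUE)
    }

    list(sequences = seqs, records = records, rscu = rscu_gene,
         rscu_pooled = rscu_pooled, enc_plot = encp, neutrality = nfit,
         ca = ca, correlations = cors, distance = dmat, cluster = clust,
         nj = njt)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
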