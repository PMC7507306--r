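#' Configuration for the end-to-end prospecting pipeline
#'
#' Collects every stage's parameters in one validated object; unknown
#' arguments are rejected so typos cannot silently fall back to
#' defaults.
#'
#' @param records Candidate protein records (tibble with `id`,
#'   `sequence`) or a FASTA path.
#' @param reference Bait/reference record (one-row tibble) or FASTA
#'   path with a single entry.
#' @param curated_labels Optional tibble (`id`, `form`) of curated form
#'   assignments used for label propagation; ids must be present among
#'   `records`.
#' @param usage Optional codon-usage table for the gene-design stage;
#'   when `NULL` the stage is skipped.
#' @param curation A [curation_config()].
#' @param form_threshold Identity threshold for the form-assignment
#'   clustering (default 0.70).
#' @param representative_threshold Identity threshold for the
#'   representative-selection clustering (default 0.90).
#' @param trim_occupancy Strict column-occupancy bound for alignment
#'   trimming (default 0.95).
#' @param gc_max,cai_min Gene-design constraints (defaults 0.60 / 0.60).
#' @param out_dir Optional directory; when given, stage outputs are
#'   written as FASTA/TSV plus a JSON summary.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(records, reference, curated_labels = NULL,
                            usage = NULL,
                            curation = curation_config(),
                            form_threshold = 0.70,
                            representative_threshold = 0.90,
                            trim_occupancy = 0.95,
                            gc_max = 0.60, cai_min = 0.60,
                            out_dir = NULL) {
  if (is.character(records)) records <- read_fasta(records)
  if (is.character(reference)) reference <- read_fasta(reference)
  check_records(records)
  structure(
    list(
      records = records, reference = reference,
      curated_labels = curated_labels, usage = usage,
      curation = curation, form_threshold = form_threshold,
      representative_threshold = representative_threshold,
      trim_occupancy = trim_occupancy,
      gc_max = gc_max, cai_min = cai_min, out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

#' Run the sequence-to-gene prospecting pipeline
#'
#' Orchestrates the deterministic chain: curation funnel, greedy
#' clustering at the form-assignment threshold, centroid alignment,
#' trimming, neighbor-joining tree, curated-label propagation with
#' cluster-level inheritance, removal of non-carboxylating form-IV
#' sequences, re-clustering at the representative threshold, and
#' (optionally) constrained reverse translation of the representatives.
#' Stages that need more input than supplied (no curated labels, fewer
#' than three clusters for a tree, no usage table) are skipped and
#' recorded as such in the summary.
#'
#' @param config A [pipeline_config()].
#' @return List with stage outputs (`curated`, `clusters_form`,
#'   `labels`, `carboxylating`, `clusters_rep`, `representatives`,
#'   `genes`) and a `summary` list of per-stage counts.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must come from pipeline_config()")
  }
  out <- list()
  curated <- curate(config$records, config$reference, config$curation)
  out$curated <- curated
  report <- curation_report(curated)
  if (nrow(curated) == 0) {
    abort("curation removed every record; nothing to prospect")
  }

  clusters_form <- greedy_cluster(
    curated, cluster_config(threshold = config$form_threshold)
  )
  out$clusters_form <- clusters_form
  centroid_ids <- unique(clusters_form$centroid_id)
  centroids <- curated[match(centroid_ids, curated$id), , drop = FALSE]

  labels <- NULL
  if (!is.null(config$curated_labels) && length(centroid_ids) >= 3) {
    # label centroids that carry a curated member, then propagate over
    # the centroid tree; members inherit their cluster's label
    curated_map <- setNames(
      config$curated_labels$form, config$curated_labels$id
    )
    centroid_curated <- clusters_form |>
      dplyr::filter(.data$member_id %in% names(curated_map)) |>
      dplyr::mutate(form = unname(curated_map[.data$member_id])) |>
      dplyr::distinct(.data$centroid_id, .data$form)
    conflicted <- centroid_curated$centroid_id[
      duplicated(centroid_curated$centroid_id)
    ]
    centroid_curated <- centroid_curated[
      !centroid_curated$centroid_id %in% conflicted, , drop = FALSE
    ]
    if (nrow(centroid_curated) > 0) {
      msa <- star_align(centroids)
      msa <- trim_alignment(msa, config$trim_occupancy)
      tree <- nj_tree(p_distances(msa))
      centroid_labels <- propagate_forms(
        tree,
        tibble(
          id = centroid_curated$centroid_id, form = centroid_curated$form
        )
      )
      labels <- clusters_form |>
        dplyr::left_join(
          dplyr::rename(centroid_labels, centroid_form = "form"),
          by = c("centroid_id" = "id")
        ) |>
        dplyr::transmute(
          id = .data$member_id,
          form = dplyr::coalesce(.data$centroid_form, "unknown")
        )
    }
  }
  if (is.null(labels)) {
    labels <- tibble(id = curated$id, form = "unknown")
  }
  out$labels <- labels

  carboxylating <- drop_form_iv(curated, labels)
  out$carboxylating <- carboxylating

  clusters_rep <- greedy_cluster(
    carboxylating,
    cluster_config(threshold = config$representative_threshold)
  )
  out$clusters_rep <- clusters_rep
  representatives <- select_representatives(clusters_rep, carboxylating)
  out$representatives <- representatives

  genes <- NULL
  if (!is.null(config$usage)) {
    genes <- optimize_genes(
      representatives, config$usage,
      gc_max = config$gc_max, cai_min = config$cai_min
    )
  }
  out$genes <- genes

  out$summary <- list(
    input = report$input,
    curated = report$retained,
    curation_removed = setNames(
      as.list(report$counts$removed), report$counts$stage
    ),
    form_clusters = length(centroid_ids),
    form_counts = as.list(table(labels$form)),
    carboxylating = nrow(carboxylating),
    representative_clusters = length(unique(clusters_rep$centroid_id)),
    genes_designed = if (is.null(genes)) 0L else nrow(genes)
  )

  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(out, config$out_dir)
  }
  out
}

write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) {
    utils::write.table(
      x, file.path(dir, name),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  write_fasta(out$curated, file.path(dir, "curated.fasta"))
  tsv(out$clusters_form, "clusters_form.tsv")
  tsv(out$labels, "form_labels.tsv")
  tsv(out$clusters_rep, "clusters_representative.tsv")
  write_fasta(out$representatives, file.path(dir, "representatives.fasta"))
  if (!is.null(out$genes)) tsv(out$genes, "designed_genes.tsv")
  jsonlite::write_json(
    out$summary, file.path(dir, "summary.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}
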