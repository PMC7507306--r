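#' Clustering settings
#'
#' @param threshold Identity fraction in `(0, 1]` a member must share with
#'   its centroid (0.70 for form assignment, 0.90 for representative
#'   selection are the thresholds this pipeline was designed around).
#' @param assignment_rule `"first-hit"` assigns a sequence to the earliest
#'   centroid meeting the threshold (USEARCH-like, default); `"best-hit"`
#'   assigns to the highest-identity qualifying centroid.
#' @param ordering `"length-descending"` (ties broken by id, default,
#'   USEARCH-like) or `"input"` order for the greedy pass.
#' @return A list of class `cluster_config`.
#' @export
cluster_config <- function(threshold = 0.9,
                           assignment_rule = c("first-hit", "best-hit"),
                           ordering = c("length-descending", "input")) {
  if (!(threshold > 0 && threshold <= 1)) {
    abort("`threshold` must be in (0, 1]")
  }
  structure(
    list(
      threshold = threshold,
      assignment_rule = match.arg(assignment_rule),
      ordering = match.arg(ordering)
    ),
    class = "cluster_config"
  )
}

#' Greedy centroid clustering by global identity
#'
#' UCLUST-style greedy clustering: sequences are visited in a
#' deterministic order (length-descending, ties by id); a sequence joins
#' the first (or best) existing centroid whose global identity meets the
#' threshold, otherwise it founds a new cluster with itself as centroid.
#' By construction every member has identity >= threshold to its centroid
#' and every centroid has identity < threshold to all earlier centroids.
#'
#' @param records Deduplicated tibble with `id` and `sequence` columns.
#' @param config A [cluster_config()].
#' @return Tibble with one row per member: `cluster` (integer, creation
#'   order), `centroid_id`, `member_id`, `identity_to_centroid`, and a
#'   `threshold` attribute.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   id = c("a", "b", "c"),
#'   sequence = c("MKVLAGDERT", "MKVLAGDERV", "GGGPPPWWYF")
#' )
#' greedy_cluster(recs, cluster_config(threshold = 0.8))
greedy_cluster <- function(records, config = cluster_config()) {
  check_records(records, require_nonempty = TRUE)
  ord <- switch(config$ordering,
    "length-descending" = order(
      -nchar(records$sequence), records$id,
      method = "radix" # C-locale id tie-break, locale-independent
    ),
    "input" = seq_len(nrow(records))
  )
  recs <- records[ord, , drop = FALSE]
  centroids <- integer(0) # row indices into recs, in creation order
  assignment <- integer(nrow(recs))
  identity_to <- numeric(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    hit <- 0L
    hit_id <- 0
    for (k in seq_along(centroids)) {
      idy <- global_identity(recs$sequence[i], recs$sequence[centroids[k]])
      if (idy >= config$threshold) {
        if (config$assignment_rule == "first-hit") {
          hit <- k
          hit_id <- idy
          break
        } else if (idy > hit_id) {
          hit <- k
          hit_id <- idy
        }
      }
    }
    if (hit == 0L) {
      centroids <- c(centroids, i)
      assignment[i] <- length(centroids)
      identity_to[i] <- 1
    } else {
      assignment[i] <- hit
      identity_to[i] <- hit_id
    }
  }
  out <- tibble(
    cluster = assignment,
    centroid_id = recs$id[centroids[assignment]],
    member_id = recs$id,
    identity_to_centroid = identity_to
  )
  out <- dplyr::arrange(out, .data$cluster)
  attr(out, "threshold") <- config$threshold
  out
}

#' Select cluster representatives
#'
#' Picks one record per cluster -- its centroid -- as the representative,
#' e.g. for gene synthesis after clustering at 90 % identity.
#'
#' @param clusters Tibble from [greedy_cluster()].
#' @param records The records that were clustered.
#' @return Tibble of centroid records, one per cluster, in cluster order.
#' @export
select_representatives <- function(clusters, records) {
  check_records(records)
  cent <- unique(clusters$centroid_id)
  missing <- setdiff(cent, records$id)
  if (length(missing) > 0) {
    abort(paste0(
      "centroid id(s) missing from records: ", paste(missing, collapse = ", ")
    ))
  }
  records[match(cent, records$id), , drop = FALSE]
}
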