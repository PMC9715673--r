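# nDCG scoring of retrieval rankings against a severity ground truth.
# Relevance of ground-truth rank i in a p-item catalogue is
#   rel(i) = 1 + 0.5 * (p - i)
# (5.5 for the most similar, 1 for the least similar when p = 10), and
#   DCG_p = sum_i (2^rel_i - 1) / log2(i + 1),
# normalised by the DCG of the ground-truth order (IDCG). Truncated
# evaluation keeps the full-catalogue relevances and truncates both sums.

#' Relevance scheme for ranked catalogues
#'
#' @param p catalogue size.
#' @param min_relevance relevance of the least similar image.
#' @param step relevance difference between contiguous ranks.
#' @export
relevance_scheme <- function(p = 10L, min_relevance = 1, step = 0.5)
  structure(list(p = as.integer(p), min_relevance = min_relevance,
                 step = step), class = "relevance_scheme")

#' Assign relevance values to a ground-truth ranking
#'
#' @param ground_truth character vector of sample ids in ground-truth order
#'   (rank 1 = most similar).
#' @param scheme a [relevance_scheme()]; defaults to the scheme for
#'   `length(ground_truth)`.
#' @return named numeric vector mapping sample id to relevance.
#' @export
assign_relevance <- function(ground_truth, scheme = NULL) {
  if (anyDuplicated(ground_truth))
    stop_data("ground truth contains duplicate ids")
  if (is.null(scheme)) scheme <- relevance_scheme(length(ground_truth))
  if (length(ground_truth) != scheme$p)
    stop_data("ground truth has %d items but the scheme expects %d",
              length(ground_truth), scheme$p)
  i <- seq_len(scheme$p)
  stats::setNames(scheme$min_relevance + scheme$step * (scheme$p - i),
                  ground_truth)
}

#' Discounted cumulative gain of a ranking
#'
#' @param ranking character vector of ids in retrieved order.
#' @param relevance named relevance map (from [assign_relevance()]).
#' @param p_eval truncation depth.
#' @export
dcg <- function(ranking, relevance, p_eval = length(ranking)) {
  if (p_eval > length(ranking))
    stop_data("p_eval (%d) exceeds ranking length (%d)", p_eval,
              length(ranking))
  top <- ranking[seq_len(p_eval)]
  if (!all(top %in% names(relevance)))
    stop_data("ranking contains ids without relevance: %s",
              paste(setdiff(top, names(relevance)), collapse = ", "))
  rel <- relevance[top]
  sum((2^rel - 1) / log2(seq_len(p_eval) + 1))
}

#' Normalised discounted cumulative gain
#'
#' `DCG(ranking) / DCG(ground-truth order)`, both truncated at `p_eval`.
#' Equals 1 exactly when the first `p_eval` positions match the ground
#' truth in relevance order.
#'
#' @param ranking ids in retrieved order.
#' @param ground_truth ids in ground-truth order (rank 1 first).
#' @param scheme optional [relevance_scheme()].
#' @param p_eval truncation depth (default: full catalogue).
#' @export
ndcg <- function(ranking, ground_truth, scheme = NULL,
                 p_eval = length(ground_truth)) {
  if (!setequal(ranking, ground_truth) ||
      length(ranking) != length(ground_truth))
    stop_data("ranking and ground truth must be permutations of the same ids")
  relevance <- assign_relevance(ground_truth, scheme)
  dcg(ranking, relevance, p_eval) / dcg(ground_truth, relevance, p_eval)
}

result_label <- function(r) {
  if (!is.null(r$method_id)) return(r$method_id)
  if (!is.null(r$rater_id)) return(r$rater_id)
  stop_data("result carries neither method_id nor rater_id")
}

#' Score retrieval results and/or rater annotations over splits
#'
#' Computes nDCG per (split, method, truncation) and five-number summaries
#' per (method, truncation).
#'
#' @param splits list of `qc_split` (catalogue ids in ground-truth order).
#' @param results list of `retrieval_result` and/or rater annotations
#'   (`list(split_id, rater_id, ranking)`).
#' @param p_evals truncation depths (default Top-10 and Top-3).
#' @return `list(per_split = data.frame(split_id, method, p_eval, ndcg),
#'   summary = data.frame(method, p_eval, min, q1, median, q3, max))`.
#' @export
evaluate_methods <- function(splits, results, p_evals = c(10L, 3L)) {
  names(splits) <- vapply(splits, `[[`, "", "split_id")
  rows <- do.call(rbind, lapply(results, function(r) {
    sp <- splits[[r$split_id]]
    if (is.null(sp)) stop_data("unknown split '%s'", r$split_id)
    do.call(rbind, lapply(p_evals, function(pe)
      data.frame(split_id = r$split_id, method = result_label(r),
                 p_eval = as.integer(pe),
                 ndcg = ndcg(r$ranking, sp$catalogue_ids, p_eval = pe),
                 stringsAsFactors = FALSE)))
  }))
  summ <- do.call(rbind, lapply(split(rows, list(rows$method, rows$p_eval),
                                      drop = TRUE), function(d) {
    fv <- fivenum(d$ndcg)
    data.frame(method = d$method[1], p_eval = d$p_eval[1], min = fv[1],
               q1 = fv[2], median = fv[3], q3 = fv[4], max = fv[5],
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(per_split = rows, summary = summ)
}

#' Inter-rater ranking agreement
#'
#' Designates one rater's rankings as the reference and scores every other
#' rater's ranking of the same catalogues against it with nDCG.
#'
#' @param annotations list of `list(split_id, rater_id, ranking)`.
#' @param ground_truth_rater id of the reference rater.
#' @param p_evals truncation depths.
#' @return as [evaluate_methods()].
#' @export
interrater <- function(annotations, ground_truth_rater, p_evals = c(10L, 3L)) {
  raters <- vapply(annotations, result_label, "")
  if (!ground_truth_rater %in% raters)
    stop_data("reference rater '%s' has no annotations", ground_truth_rater)
  if (length(unique(raters)) < 2L)
    stop_data("inter-rater comparison needs at least 2 raters")
  ref <- annotations[raters == ground_truth_rater]
  ref_by_split <- stats::setNames(
    lapply(ref, `[[`, "ranking"),
    vapply(ref, `[[`, "", "split_id"))
  others <- annotations[raters != ground_truth_rater]
  rows <- do.call(rbind, lapply(others, function(a) {
    gt <- ref_by_split[[a$split_id]]
    if (is.null(gt))
      stop_data("reference rater has no ranking for split '%s'", a$split_id)
    do.call(rbind, lapply(p_evals, function(pe)
      data.frame(split_id = a$split_id, method = result_label(a),
                 p_eval = as.integer(pe),
                 ndcg = ndcg(a$ranking, gt, p_eval = pe),
                 stringsAsFactors = FALSE)))
  }))
  summ <- do.call(rbind, lapply(split(rows, list(rows$method, rows$p_eval),
                                      drop = TRUE), function(d) {
    fv <- fivenum(d$ndcg)
    data.frame(method = d$method[1], p_eval = d$p_eval[1], min = fv[1],
               q1 = fv[2], median = fv[3], q3 = fv[4], max = fv[5],
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(per_split = rows, summary = summ)
}

#' Read / write ranking annotations (CSV, one row per position)
#'
#' Format: `split_id,rater_id,rank,sample_id`.
#' @param path CSV path.
#' @export
read_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(split_id = "character",
                                rater_id = "character",
                                sample_id = "character"))
  keys <- unique(df[, c("split_id", "rater_id")])
  lapply(seq_len(nrow(keys)), function(i) {
    d <- df[df$split_id == keys$split_id[i] & df$rater_id == keys$rater_id[i], ]
    list(split_id = keys$split_id[i], rater_id = keys$rater_id[i],
         ranking = d$sample_id[order(d$rank)])
  })
}

#' @rdname read_annotations
#' @param annotations list of `list(split_id, rater_id, ranking)`.
#' @export
write_annotations <- function(annotations, path) {
  rows <- do.call(rbind, lapply(annotations, function(a)
    data.frame(split_id = a$split_id, rater_id = result_label(a),
               rank = seq_along(a$ranking), sample_id = a$ranking,
               stringsAsFactors = FALSE)))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
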