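#' Jaccard distance between two sets
#'
#' One minus intersection over union, on unique elements. Undefined (an
#' error) when both sets are empty.
#'
#' @param a,b character vectors treated as sets.
#' @return numeric in [0, 1].
#' @examples
#' jaccardDistance(c("A", "B", "C"), c("B", "C", "D"))  # 0.5
#' @export
jaccardDistance <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) stop("undefined distance: both sets empty")
  1 - length(intersect(a, b)) / u
}

#' Rank compartment markers by prey-profile similarity
#'
#' Compares a bait's (high-confidence) prey set against each marker bait of
#' a compartment compendium by Jaccard distance and returns markers ranked
#' from most to least similar. Genes on the exclusion list (typically preys
#' with no annotated function or localization) are removed from both the
#' query and every marker set before comparison. Ties in distance are broken
#' lexicographically by marker bait name.
#'
#' @param queryPreys character vector of prey symbols (e.g. from
#'   \code{\link{highConfidencePreys}}).
#' @param compendium data.frame with columns marker_bait, compartment, prey
#'   (see \code{\link{readCompendium}}).
#' @param exclude character vector of genes to drop from both sides.
#' @return data.frame with columns marker_bait, compartment,
#'   jaccard_distance, sorted ascending by distance.
#' @export
rankCompartments <- function(queryPreys, compendium, exclude = character()) {
  if (!nrow(compendium)) stop("empty compendium")
  query <- setdiff(unique(queryPreys), exclude)
  if (!length(query)) stop("query prey set empty after exclusion")
  markers <- unique(compendium[, c("marker_bait", "compartment")])
  d <- vapply(markers$marker_bait, function(mb) {
    set <- setdiff(unique(compendium$prey[compendium$marker_bait == mb]), exclude)
    if (!length(set)) return(1)
    jaccardDistance(query, set)
  }, 0)
  out <- data.frame(marker_bait = markers$marker_bait,
                    compartment = markers$compartment,
                    jaccard_distance = unname(d), stringsAsFactors = FALSE)
  out <- out[order(out$jaccard_distance, out$marker_bait), , drop = FALSE]
  rownames(out) <- NULL
  out
}
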