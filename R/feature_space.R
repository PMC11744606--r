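# Structured (charge / spatial position / radius) feature vectors and the
# Euclidean distance layer between epitopes.

#' Build a structured feature vector from a residue table
#'
#' Flattens selected per-residue components into one numeric vector: for each
#' row (in table order) the chosen components are appended in the fixed order
#' charge, x, y, z, radius. Anchor trimming removes the epitope residues at
#' peptide positions 2 and 9 (the HLA-binding anchors, largely hidden from
#' the TCR) before flattening.
#'
#' @param rows Residue feature data.frame ([aggregate_residues()] output).
#' @param scope Structural scope applied first; see [apply_scope()].
#' @param components Character subset of `c("c", "XYZ", "r")`.
#' @param trimmed Drop epitope anchor positions P2 and P9?
#' @param epitope_id Identifier carried on the vector.
#' @return A `FeatureVector`: list with `epitope_id`, `scope`, `components`,
#'   `trimmed` and the numeric `values`.
#' @export
build_feature_vector <- function(rows, scope = "EPITOPE",
                                 components = c("c", "XYZ"),
                                 trimmed = FALSE,
                                 epitope_id = NA_character_) {
  components <- unique(components)
  if (length(components) == 0L) stop("empty component set", call. = FALSE)
  bad <- setdiff(components, c("c", "XYZ", "r"))
  if (length(bad)) stop("unknown component(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  rows <- apply_scope(rows, scope)
  if (trimmed) {
    epi <- rows$role == "EPITOPE"
    if (!any(epi)) {
      stop("anchor trimming requires a scope containing the epitope",
           call. = FALSE)
    }
    pos <- rows$residue_number - min(rows$residue_number[epi]) + 1L
    drop <- epi & pos %in% c(2L, 9L)
    rows <- rows[!drop, ]
  }
  cols <- c(if ("c" %in% components) "charge",
            if ("XYZ" %in% components) c("x", "y", "z"),
            if ("r" %in% components) "radius")
  values <- as.numeric(t(as.matrix(rows[, cols, drop = FALSE])))
  structure(
    list(epitope_id = epitope_id, scope = scope,
         components = sort(components), trimmed = trimmed, values = values),
    class = "FeatureVector"
  )
}

# Configurations must match before distances are meaningful.
check_fv_compatible <- function(u, v) {
  stopifnot(inherits(u, "FeatureVector"), inherits(v, "FeatureVector"))
  if (!identical(u$scope, v$scope) ||
      !identical(u$components, v$components) ||
      !identical(u$trimmed, v$trimmed) ||
      length(u$values) != length(v$values)) {
    stop("feature vectors have mismatched configuration", call. = FALSE)
  }
  invisible(TRUE)
}

#' Euclidean distance between two feature vectors
#' @param u,v `FeatureVector`s with identical scope/components/trim.
#' @export
euclidean_distance <- function(u, v) {
  check_fv_compatible(u, v)
  sqrt(sum((u$values - v$values)^2))
}

#' All unique pairwise distances between feature vectors
#'
#' @param vectors List of `FeatureVector`s with distinct `epitope_id`s and a
#'   uniform configuration.
#' @param origins Optional named character vector (`epitope_id -> origin`)
#'   used to attach a `pair_class` column such as `"HV"` for a human/viral
#'   pair (class letters: H = self/human, V = viral, T = tumor; ordered
#'   alphabetically within the pair except tumor-first pairs `TH`/`TV`).
#' @return Data.frame with `id_a`, `id_b` (canonical order: `id_a < id_b`),
#'   `distance`, and optionally `pair_class`; `n(n-1)/2` rows.
#' @export
pairwise_distance_table <- function(vectors, origins = NULL) {
  stopifnot(is.list(vectors), length(vectors) >= 2L)
  ids <- vapply(vectors, function(v) v$epitope_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate epitope_id", call. = FALSE)
  for (v in vectors[-1]) check_fv_compatible(vectors[[1]], v)
  mat <- do.call(rbind, lapply(vectors, `[[`, "values"))
  rownames(mat) <- ids
  d <- as.matrix(stats::dist(mat, method = "euclidean"))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  out <- data.frame(
    id_a = pmin(ids[idx[, 1]], ids[idx[, 2]]),
    id_b = pmax(ids[idx[, 1]], ids[idx[, 2]]),
    distance = d[idx],
    stringsAsFactors = FALSE
  )
  if (!is.null(origins)) out$pair_class <- pair_class(origins[out$id_a],
                                                      origins[out$id_b])
  out[order(out$id_a, out$id_b), , drop = FALSE]
}

#' Origin-pair class label for a pair of epitopes
#'
#' @param origin_a,origin_b Origin labels among `"SELF"`, `"VIRAL"`,
#'   `"TUMOR"`.
#' @return `"HH"`, `"HV"`, `"VV"`, `"TH"`, `"TV"` or `"TT"`.
#' @export
pair_class <- function(origin_a, origin_b) {
  code <- c(SELF = "H", VIRAL = "V", TUMOR = "T")
  a <- code[origin_a]
  b <- code[origin_b]
  if (anyNA(a) || anyNA(b)) stop("unknown origin label", call. = FALSE)
  # tumor is listed first; other pairs alphabetically
  swap <- (b == "T" & a != "T") | (a != "T" & b != "T" & a > b)
  lab <- paste0(ifelse(swap, b, a), ifelse(swap, a, b))
  unname(lab)
}
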