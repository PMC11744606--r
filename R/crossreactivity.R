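# Cross-reactive CDR3 identification from TCR-epitope assay tables, and the
# distance statistics contrasting their epitope sets with background pools.
#
# A CDR3 (the hypervariable TCR loop dominating epitope contact) is called
# cross-reactive when it is associated with at least two distinct epitopes
# that survive the study filters (human, MHC class I, nonamer, HLA-A*02).

# Column maps for the common public-database dialects. Each maps the
# canonical record fields to the column names of that source.
TCR_DIALECTS <- list(
  generic = c(cdr3_alpha = "cdr3_alpha", cdr3_beta = "cdr3_beta",
              epitope = "epitope", allele = "allele", species = "species",
              mhc_class = "mhc_class"),
  vdjdb = c(cdr3_alpha = "cdr3.alpha", cdr3_beta = "cdr3.beta",
            epitope = "antigen.epitope", allele = "mhc.a",
            species = "species", mhc_class = "mhc.class"),
  mcpas = c(cdr3_alpha = "CDR3.alpha.aa", cdr3_beta = "CDR3.beta.aa",
            epitope = "Epitope.peptide", allele = "MHC",
            species = "Species", mhc_class = "MHC.class"),
  tbadb = c(cdr3_alpha = "CDR3.alpha", cdr3_beta = "CDR3.beta",
            epitope = "Antigen.sequence", allele = "HLA",
            species = "Species", mhc_class = "MHC.class")
)

#' Load and filter a TCR-epitope assay table
#'
#' Applies, in order, the species, MHC-class, epitope-length (nonamer) and
#' allele filters; per-filter drop counts are attached as the `drop_counts`
#' attribute.
#'
#' @param source TSV path or a data.frame.
#' @param dialect One of `"generic"`, `"vdjdb"`, `"mcpas"`, `"tbadb"`, or a
#'   named character vector giving a custom column map.
#' @param species Accepted species labels.
#' @param mhc_class Accepted MHC class labels.
#' @param alleles Accepted allele annotations.
#' @param epitope_length Required epitope length (9 for nonamers).
#' @return Data.frame of records with canonical columns `cdr3_alpha`,
#'   `cdr3_beta`, `epitope`, `allele`, `species`, `mhc_class`.
#' @export
load_tcr_table <- function(source, dialect = "generic",
                           species = c("Human", "HomoSapiens",
                                       "Homo Sapiens"),
                           mhc_class = c("MHC-I", "MHCI", "I"),
                           alleles = c("HLA-A*02:01", "HLA-A*02"),
                           epitope_length = 9L) {
  cmap <- if (is.character(dialect) && length(dialect) == 1L) {
    if (!dialect %in% names(TCR_DIALECTS)) {
      stop("unknown dialect: ", dialect, call. = FALSE)
    }
    TCR_DIALECTS[[dialect]]
  } else dialect
  df <- if (is.character(source)) {
    utils::read.table(source, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      quote = "", comment.char = "")
  } else as.data.frame(source, stringsAsFactors = FALSE)

  missing_cols <- setdiff(unname(cmap), names(df))
  if (length(missing_cols)) {
    stop("missing mapped column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  rec <- setNames(df[unname(cmap)], names(cmap))
  rec$cdr3_alpha[!nzchar(trimws(rec$cdr3_alpha %||% ""))] <- NA_character_
  rec$cdr3_beta[!nzchar(trimws(rec$cdr3_beta %||% ""))] <- NA_character_

  drops <- c(species = 0L, mhc_class = 0L, length = 0L, allele = 0L,
             no_cdr3 = 0L)
  keep <- rec$species %in% species
  drops["species"] <- sum(!keep); rec <- rec[keep, ]
  keep <- rec$mhc_class %in% mhc_class
  drops["mhc_class"] <- sum(!keep); rec <- rec[keep, ]
  keep <- nchar(rec$epitope) == epitope_length
  drops["length"] <- sum(!keep); rec <- rec[keep, ]
  keep <- rec$allele %in% alleles
  drops["allele"] <- sum(!keep); rec <- rec[keep, ]
  keep <- !(is.na(rec$cdr3_alpha) & is.na(rec$cdr3_beta))
  drops["no_cdr3"] <- sum(!keep); rec <- rec[keep, ]

  rownames(rec) <- NULL
  attr(rec, "drop_counts") <- drops
  rec
}

#' Group records into cross-reactive CDR3 sets
#'
#' Records are grouped by CDR3 key — the alpha/beta pair when both chains are
#' present (`chain = "paired"`), or a single chain — and groups associated
#' with at least two distinct epitopes are returned, largest first.
#'
#' @param records Filtered records from [load_tcr_table()].
#' @param chain `"paired"`, `"alpha"` or `"beta"`.
#' @return List of `CrossReactiveSet`s: each a list with `cdr3_key` and the
#'   character vector `epitopes` (sorted, length >= 2). Ordered by epitope
#'   count descending, then key.
#' @export
find_crossreactive <- function(records, chain = c("paired", "alpha", "beta")) {
  chain <- match.arg(chain)
  key <- switch(chain,
    paired = ifelse(!is.na(records$cdr3_alpha) & !is.na(records$cdr3_beta),
                    paste(records$cdr3_alpha, records$cdr3_beta, sep = "|"),
                    ifelse(is.na(records$cdr3_beta),
                           records$cdr3_alpha, records$cdr3_beta)),
    alpha = records$cdr3_alpha,
    beta = records$cdr3_beta
  )
  ok <- !is.na(key)
  sets <- tapply(records$epitope[ok], key[ok],
                 function(e) sort(unique(e)), simplify = FALSE)
  sets <- sets[vapply(sets, length, integer(1)) >= 2L]
  if (length(sets) == 0L) return(list())
  ord <- order(-vapply(sets, length, integer(1)), names(sets))
  lapply(ord, function(i) {
    structure(list(cdr3_key = names(sets)[i], epitopes = sets[[i]]),
              class = "CrossReactiveSet")
  })
}

#' Percent sequence identity of two ungapped equal-length peptides
#'
#' PID1-style identity: `100 * matching positions / length`. No alignment is
#' performed; unequal lengths are an error.
#'
#' @param a,b Peptide strings of equal length.
#' @return Identity in `[0, 100]`.
#' @export
percent_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  if (length(ca) != length(cb)) {
    stop("sequences differ in length (", length(ca), " vs ", length(cb),
         "); percent_identity is ungapped", call. = FALSE)
  }
  100 * sum(ca == cb) / length(ca)
}

#' Pairwise identity profile of a cross-reactive epitope set
#'
#' @param set A `CrossReactiveSet` (or character vector of epitopes).
#' @return Numeric vector of identities, one per unordered epitope pair.
#' @export
crossreactive_identity_profile <- function(set) {
  epitopes <- if (inherits(set, "CrossReactiveSet")) set$epitopes else set
  stopifnot(length(epitopes) >= 2L)
  pairs <- utils::combn(epitopes, 2L)
  apply(pairs, 2L, function(p) percent_identity(p[1], p[2]))
}

#' Position frequency matrix of nonamer epitopes
#'
#' @param epitopes Character vector of nonamers.
#' @return 20 x 9 matrix (residues x positions); each column sums to 1.
#' @export
position_frequency_matrix <- function(epitopes) {
  if (any(nchar(epitopes) != 9L)) stop("all epitopes must be nonamers",
                                       call. = FALSE)
  chars <- do.call(rbind, strsplit(epitopes, ""))
  out <- matrix(0, nrow = 20L, ncol = 9L,
                dimnames = list(AMINO_ACIDS, paste0("P", 1:9)))
  for (j in 1:9) {
    tab <- table(factor(chars[, j], levels = AMINO_ACIDS))
    out[, j] <- as.numeric(tab) / length(epitopes)
  }
  out
}

#' Compare target distances with a background pool
#'
#' Two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction) plus Cohen's d effect size and group medians — the statistic
#' used to ask whether epitopes recognized by one cross-reactive CDR3 sit
#' closer together in distance space than unrelated epitopes.
#'
#' @param target_distances,pool_distances Non-empty numeric vectors.
#' @param effect_on `"raw"` or `"ranks"` for the Cohen's d computation.
#' @return List with `median_target`, `median_pool`, `p_value`,
#'   `effect_size`.
#' @export
compare_to_pool <- function(target_distances, pool_distances,
                            effect_on = c("raw", "ranks")) {
  effect_on <- match.arg(effect_on)
  if (length(target_distances) == 0L || length(pool_distances) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  wt <- stats::wilcox.test(target_distances, pool_distances,
                           alternative = "two.sided",
                           exact = FALSE, correct = TRUE)
  list(
    median_target = stats::median(target_distances),
    median_pool = stats::median(pool_distances),
    p_value = wt$p.value,
    effect_size = if (length(target_distances) < 2L ||
                      length(pool_distances) < 2L) NA_real_
                  else cohens_d(target_distances, pool_distances,
                                on_ranks = effect_on == "ranks")
  )
}
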