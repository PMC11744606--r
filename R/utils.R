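# Internal helpers shared across modules.

AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

CHAIN_ROLES <- c("HLA", "B2M", "EPITOPE")

SCOPES <- c("PHLA", "EC_PHLA", "EPITOPE")

PERSPECTIVES <- c("TOP", "XP10", "XM10", "YP10", "YM10")

# Net side-chain charge at pH 7, coarse-grained to the acid/basic/neutral
# level that drives the surface colouring.
RESIDUE_CHARGE <- c(
  A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 0.1, I = 0, K = 1,
  L = 0, M = 0, N = 0, P = 0, Q = 0, R = 1, S = 0, T = 0, V = 0,
  W = 0, Y = 0
)

# Approximate side-chain heavy-atom counts; used to give each residue a
# distinctive (deterministic) pseudo-atom geometry and radius.
RESIDUE_SIZE <- c(
  A = 1, C = 2, D = 4, E = 5, F = 7, G = 0, H = 6, I = 4, K = 5,
  L = 4, M = 4, N = 4, P = 3, Q = 5, R = 7, S = 2, T = 3, V = 3,
  W = 10, Y = 8
)

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
#' @noRd
assert_peptide <- function(seq, len = NULL, arg = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop(arg, " must be a single peptide string", call. = FALSE)
  }
  chars <- strsplit(seq, "")[[1]]
  bad <- setdiff(chars, AMINO_ACIDS)
  if (length(bad)) {
    stop(arg, " contains non-standard residue letter(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  if (!is.null(len) && length(chars) != len) {
    stop(arg, " must be a ", len, "-mer, got length ", length(chars),
         call. = FALSE)
  }
  invisible(chars)
}

# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Small deterministic integer hash of a string, for per-sequence seed offsets.
# Kept below 2^31 so it is always a valid set.seed() argument.
string_seed <- function(x, base = 0L) {
  h <- 0
  for (ch in utf8ToInt(x)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(base) + h) %% .Machine$integer.max)
}

# Cohen's d with pooled standard deviation; rank variant ranks the joint
# sample first (robust analogue used for distance distributions).
cohens_d <- function(a, b, on_ranks = FALSE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (on_ranks) {
    r <- rank(c(a, b))
    a <- r[seq_along(a)]
    b <- r[-seq_along(a)]
  }
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) return(0)
  (mean(a) - mean(b)) / sqrt(sp2)
}
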