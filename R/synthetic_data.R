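# Deterministic synthetic-data generator.
#
# Emulates every upstream stage the pipeline consumes but does not compute:
# docked pHLA structures (fixed template topology: 276 HLA + 99 B2M + 9
# epitope residues), electrostatic surface renders (charge-coloured Gaussian
# splats from five perspectives), TCR-epitope assay tables with planted
# cross-reactive CDR3s, activation assays with a planted monotone
# distance -> readout relationship, and self/viral/tumor epitope pools with
# exact planted overlap and mimicry structure. Every generator is a pure
# function of (config, seed); the planted quantities are what the pipeline
# stages are tested against.

AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
         H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
         P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
         W = "TRP", Y = "TYR")

#' Synthetic-study configuration
#'
#' Bundles the generator settings: cohort sizes mirror the modeled study
#' cohort (989 self, 987 viral, 133 tumor epitopes), the template topology
#' totals 384 residues, images default to 640x480 with the five standard
#' perspectives, and the planted activation model is a non-positive slope
#' plus Gaussian noise.
#'
#' @param seed Master seed; fully determines all generated data.
#' @param n_self,n_viral,n_tumor Pool sizes.
#' @param shared_fraction Fraction of self sequences copied into the viral
#'   pool (the planted census overlap).
#' @param mimic_self_fraction Fraction of tumor epitopes planted as mimics
#'   of a self (vs viral) epitope.
#' @param hla_residues,b2m_residues,peptide_length Chain topology.
#' @param image_size `c(width, height)` of rendered surfaces.
#' @param planted_slope Activation-model slope (must be <= 0).
#' @param noise_sd Activation-model noise SD.
#' @export
synthetic_config <- function(seed = 1L, n_self = 989L, n_viral = 987L,
                             n_tumor = 133L, shared_fraction = 0.01,
                             mimic_self_fraction = 0.6,
                             hla_residues = 276L, b2m_residues = 99L,
                             peptide_length = 9L,
                             image_size = c(640L, 480L),
                             planted_slope = -1, noise_sd = 0.5) {
  if (planted_slope > 0) stop("planted_slope must be <= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop("shared_fraction must be in [0, 1]", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed), n_self = n_self, n_viral = n_viral,
    n_tumor = n_tumor, shared_fraction = shared_fraction,
    mimic_self_fraction = mimic_self_fraction,
    hla_residues = hla_residues, b2m_residues = b2m_residues,
    peptide_length = peptide_length, image_size = image_size,
    perspectives = PERSPECTIVES, planted_slope = planted_slope,
    noise_sd = noise_sd
  ), class = "synthetic_config")
}

# Fixed pseudo-sequence of the template chains: residue identity is a
# deterministic function of the residue index, shared by every structure.
template_residue <- function(i) AMINO_ACIDS[(i * 7L) %% 20L + 1L]

# Deterministic side-chain centroid offset per residue identity; gives each
# sequence a reproducible geometric signature on top of the backbone.
sidechain_offset <- function(aa) {
  s <- RESIDUE_SIZE[aa]
  k <- match(aa, AMINO_ACIDS)
  c(0.15 * s * cos(k), 0.15 * s * sin(k), 0.35 + 0.05 * s)
}

# The HLA + B2M scaffold is the same in every structure (fixed docking
# template); build it once per topology and cache it. Scaffold residues are
# charge-neutral so every colour difference between two renders — and every
# feature-space distance — is attributable to the peptide, which is the
# planted signal the pipeline stages are tested against.
.template_cache <- new.env(parent = emptyenv())

template_atoms <- function(config) {
  key <- paste(config$hla_residues, config$b2m_residues, sep = "_")
  if (!is.null(.template_cache[[key]])) return(.template_cache[[key]])
  one_chain <- function(chain, n, center_fn, aa_fn) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      aa <- aa_fn(i)
      off <- sidechain_offset(aa)
      center <- center_fn(i)
      k <- 1:3
      data.frame(
        atom_name = c("CA", "CB", "CG"),
        residue_name = AA3[[aa]],
        chain_id = chain, residue_number = i,
        x = center[1] + c(0, off[1] * (k[-1] - 0.5) / 3),
        y = center[2] + c(0, off[2] * (k[-1] - 0.5) / 3),
        z = center[3] + c(0, off[3] * (k[-1] - 0.5) / 3),
        charge = 0,
        radius = 1.2 + 0.08 * RESIDUE_SIZE[[aa]],
        stringsAsFactors = FALSE
      )
    }))
  }
  hla <- one_chain("A", config$hla_residues, function(i) {
    # folded path around the groove, extracellular part (<= 180) on top
    c(22 * sin(i * 0.19), 16 * cos(i * 0.23),
      if (i <= 180) -1 - 0.02 * i else -12 - 0.15 * (i - 180))
  }, function(i) template_residue(i))
  b2m <- one_chain("B", config$b2m_residues, function(i) {
    # compact domain displaced below the platform
    c(10 * sin(i * 0.31) - 8, 10 * cos(i * 0.29) + 6, -20 - 0.1 * i)
  }, function(i) template_residue(i + 500L))
  out <- rbind(hla, b2m)
  .template_cache[[key]] <- out
  out
}

#' Generate a docked pHLA structure for a nonamer
#'
#' Fixed template backbone for the HLA heavy chain (chain A, residues
#' 1..276) and beta-2-microglobulin (chain B, 1..99); the peptide (chain C)
#' lies along the groove axis at ~3.3 A spacing. Each peptide residue
#' contributes 2-4 pseudo-atoms carrying its net charge at pH 7 (D/E -1,
#' K/R +1, H +0.1, others 0) split equally, with identity-dependent
#' side-chain geometry and radius; the scaffold chains are charge-neutral,
#' so differences between structures are attributable to the peptide.
#' Deterministic given (sequence, seed).
#'
#' @param sequence Nonamer peptide string.
#' @param config A [synthetic_config()].
#' @return An annotated `StructureTable`; the sequence is kept in the
#'   `epitope_id` attribute.
#' @export
generate_phla_structure <- function(sequence, config = synthetic_config()) {
  chars <- assert_peptide(sequence, len = config$peptide_length)

  res_atoms <- function(chain, resnum, aa, center, n_atoms, charge) {
    off <- sidechain_offset(aa)
    k <- seq_len(n_atoms)
    data.frame(
      atom_name = c("CA", "CB", "CG", "CD")[k],
      residue_name = AA3[[aa]],
      chain_id = chain,
      residue_number = resnum,
      x = center[1] + c(0, off[1] * (k[-1] - 0.5) / n_atoms),
      y = center[2] + c(0, off[2] * (k[-1] - 0.5) / n_atoms),
      z = center[3] + c(0, off[3] * (k[-1] - 0.5) / n_atoms),
      charge = charge / n_atoms,
      radius = 1.2 + 0.08 * RESIDUE_SIZE[[aa]],
      stringsAsFactors = FALSE
    )
  }

  blocks <- list(template_atoms(config))
  # peptide along the groove axis, slightly above the platform
  for (i in seq_along(chars)) {
    aa <- chars[i]
    n_atoms <- 2L + (RESIDUE_SIZE[[aa]] > 3) + (RESIDUE_SIZE[[aa]] > 6)
    center <- c(3.3 * (i - (length(chars) + 1) / 2), 0, 2)
    blocks[[length(blocks) + 1L]] <-
      res_atoms("C", i, aa, center, n_atoms, RESIDUE_CHARGE[[aa]])
  }

  atoms <- do.call(rbind, blocks)
  atoms$atom_index <- seq_len(nrow(atoms))
  atoms <- atoms[, c("atom_index", "atom_name", "residue_name", "chain_id",
                     "residue_number", "x", "y", "z", "charge", "radius")]
  rownames(atoms) <- NULL
  tab <- structure(list(atoms = atoms,
                        role_map = c(A = "HLA", B = "B2M", C = "EPITOPE")),
                   class = "StructureTable")
  attr(tab, "epitope_id") <- sequence
  tab
}

# Rotation matrices for the five perspectives: the top view plus +-10
# degree tilts about the x and y axes.
perspective_rotation <- function(perspective) {
  deg <- pi / 18  # 10 degrees
  rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                           3, byrow = TRUE)
  ry <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)),
                           3, byrow = TRUE)
  switch(perspective,
         TOP = diag(3),
         XP10 = rx(deg), XM10 = rx(-deg),
         YP10 = ry(deg), YM10 = ry(-deg),
         stop("unknown perspective: ", perspective, call. = FALSE))
}

#' Render the electrostatic surface of a synthetic pHLA
#'
#' Projects the extracellular residues through the perspective's rotation
#' onto the image grid and splats each residue as a 2-D Gaussian: negative
#' charge adds red, positive charge adds blue, neutral residues stay white;
#' intensities are clamped to a symmetric scale (the +-10 kT convention).
#' Alpha is 1 inside the molecular footprint and 0 outside. The projected
#' pixel region of each peptide position is attached as the
#' `position_regions` attribute (named list `P1`..`P9` of pixel indices).
#'
#' @param struct A `StructureTable` from [generate_phla_structure()].
#' @param perspective One of `"TOP"`, `"XP10"`, `"XM10"`, `"YP10"`,
#'   `"YM10"`.
#' @param config A [synthetic_config()]; `image_size` sets the raster.
#' @return A `SurfaceImage` (see [decompose_image()] for the layout).
#' @export
render_surface <- function(struct, perspective = "TOP",
                           config = synthetic_config()) {
  rot <- perspective_rotation(perspective)
  rows <- apply_scope(aggregate_residues(struct), "EC_PHLA")
  xyz <- as.matrix(rows[, c("x", "y", "z")]) %*% t(rot)

  W <- config$image_size[1]
  H <- config$image_size[2]
  # fixed world window; the complex sits centered with margin
  px <- 1 + (xyz[, 1] + 30) / 60 * (W - 1)
  py <- 1 + (xyz[, 2] + 24) / 48 * (H - 1)
  sigma <- 0.018 * W

  neg <- matrix(0, W, H)
  pos <- matrix(0, W, H)
  fp <- matrix(0, W, H)
  half <- ceiling(3 * sigma)
  for (i in seq_len(nrow(rows))) {
    cx <- px[i]; cy <- py[i]
    ix <- max(1L, floor(cx - half)):min(W, ceiling(cx + half))
    iy <- max(1L, floor(cy - half)):min(H, ceiling(cy + half))
    if (!length(ix) || !length(iy)) next
    g <- exp(-outer((ix - cx)^2, (iy - cy)^2, "+") / (2 * sigma^2))
    fp[ix, iy] <- fp[ix, iy] + g
    q <- rows$charge[i]
    if (q < 0) neg[ix, iy] <- neg[ix, iy] - q * g
    if (q > 0) pos[ix, iy] <- pos[ix, iy] + q * g
  }

  inside <- fp > 0.05
  neg <- pmin(neg, 1)   # symmetric clamp, +-10 kT analogue
  pos <- pmin(pos, 1)
  red <- ifelse(inside, 1 - pos, 0)
  green <- ifelse(inside, pmax(0, 1 - pos - neg), 0)
  blue <- ifelse(inside, 1 - neg, 0)
  alpha <- ifelse(inside, 1, 0)

  img <- structure(
    list(epitope_id = attr(struct, "epitope_id") %||% NA_character_,
         perspective = perspective,
         red = red, green = green, blue = blue, alpha = alpha),
    class = "SurfaceImage"
  )
  img$composite <- composite(img)

  # peptide position footprints for the variant difference map
  epi <- rows$role == "EPITOPE"
  regions <- lapply(which(epi), function(i) {
    ix <- max(1L, floor(px[i] - 2 * sigma)):min(W, ceiling(px[i] + 2 * sigma))
    iy <- max(1L, floor(py[i] - 2 * sigma)):min(H, ceiling(py[i] + 2 * sigma))
    as.integer(outer(ix, (iy - 1L) * W, "+"))
  })
  names(regions) <- paste0("P", rows$residue_number[epi])
  attr(img, "position_regions") <- regions
  img
}

#' Write a surface image as PNG
#' @param img A `SurfaceImage`.
#' @param path Output path.
#' @export
write_surface_png <- function(img, path) {
  arr <- array(0, dim = c(ncol(img$red), nrow(img$red), 4L))
  arr[, , 1] <- t(img$red)
  arr[, , 2] <- t(img$green)
  arr[, , 3] <- t(img$blue)
  arr[, , 4] <- t(img$alpha)
  png::writePNG(arr, path)
  invisible(path)
}

# Random A*02-style nonamer (anchor-compatible P2/P9); vectorized count.
random_nonamers <- function(n, anchored = TRUE) {
  body <- function() paste(sample(AMINO_ACIDS, 7L, replace = TRUE),
                           collapse = "")
  vapply(seq_len(n), function(i) {
    mid <- body()
    if (anchored) {
      paste0(substr(mid, 1, 1), sample(c("L", "M"), 1L),
             substr(mid, 2, 7), sample(c("V", "L", "I"), 1L))
    } else {
      paste0(mid, paste(sample(AMINO_ACIDS, 2L, replace = TRUE),
                        collapse = ""))
    }
  }, character(1))
}

# Conservative substitution: same net charge, similar size. Used to plant
# tumor mimics one benign step away from their parent epitope.
CONSERVATIVE_SUB <- c(
  A = "V", V = "A", I = "L", L = "I", S = "T", T = "S", F = "Y", Y = "F",
  D = "E", E = "D", K = "R", R = "K", N = "Q", Q = "N", G = "A", P = "G",
  W = "F", M = "L", C = "S", H = "N"
)

#' Generate a TCR-epitope assay table with planted cross-reactive CDR3s
#'
#' Emulates the public-database tables after export: paired CDR3
#' alpha/beta, epitope, allele, species and MHC class columns. Plants two
#' promiscuous CDR3 pairs recognizing 12 and 10 epitopes whose sequences
#' share residues at positions 3, 6 and 7 but are otherwise random (low
#' overall identity), plus smaller cross-reactive sets, single-epitope
#' background CDR3s, and decoy rows that each fail exactly one study filter
#' (wrong species, MHC class II, 10-mer epitope, non-A*02 allele).
#'
#' @param config A [synthetic_config()].
#' @param n_background Single-epitope CDR3s passing all filters.
#' @param n_cross Additional cross-reactive CDR3s (2-4 epitopes each).
#' @param n_decoys Decoy rows per failing filter.
#' @return Data.frame in the `"generic"` dialect of [load_tcr_table()].
#'   The planted promiscuous sets are attached as the `planted_sets`
#'   attribute.
#' @export
generate_tcr_table <- function(config = synthetic_config(),
                               n_background = 60L, n_cross = 8L,
                               n_decoys = 5L) {
  with_seed(config$seed + 101L, {
    rand_cdr3 <- function(prefix = "CASS") {
      paste0(prefix, paste(sample(AMINO_ACIDS, 7L, replace = TRUE),
                           collapse = ""), "F")
    }
    motif_epitope <- function(motif) {
      chars <- sample(AMINO_ACIDS, 9L, replace = TRUE)
      chars[c(3L, 6L, 7L)] <- motif
      paste(chars, collapse = "")
    }
    planted_row <- function(alpha, beta, epitope) {
      data.frame(cdr3_alpha = alpha, cdr3_beta = beta, epitope = epitope,
                 allele = "HLA-A*02:01", species = "Human",
                 mhc_class = "MHC-I", stringsAsFactors = FALSE)
    }

    rows <- list()
    planted_sets <- list()
    # two promiscuous CDR3s: 12 and 10 epitopes sharing a 3/6/7 motif
    for (sz in c(12L, 10L)) {
      alpha <- rand_cdr3("CAL")
      beta <- rand_cdr3("CASS")
      motif <- sample(AMINO_ACIDS, 3L)
      eps <- character(0)
      while (length(eps) < sz) eps <- unique(c(eps, motif_epitope(motif)))
      planted_sets[[length(planted_sets) + 1L]] <-
        list(cdr3_key = paste(alpha, beta, sep = "|"), epitopes = eps)
      for (e in eps) rows[[length(rows) + 1L]] <- planted_row(alpha, beta, e)
    }
    # smaller cross-reactive sets
    for (i in seq_len(n_cross)) {
      alpha <- rand_cdr3("CAL"); beta <- rand_cdr3("CASS")
      eps <- unique(random_nonamers(sample(2:4, 1L)))
      for (e in eps) rows[[length(rows) + 1L]] <- planted_row(alpha, beta, e)
    }
    # single-epitope background
    for (i in seq_len(n_background)) {
      rows[[length(rows) + 1L]] <-
        planted_row(rand_cdr3("CAL"), rand_cdr3("CASS"),
                    random_nonamers(1L))
    }
    # decoys: each fails exactly one filter
    for (i in seq_len(n_decoys)) {
      r <- planted_row(rand_cdr3("CAL"), rand_cdr3("CASS"),
                       random_nonamers(1L))
      r$species <- "MusMusculus"
      rows[[length(rows) + 1L]] <- r
      r <- planted_row(rand_cdr3("CAL"), rand_cdr3("CASS"),
                       random_nonamers(1L))
      r$mhc_class <- "MHC-II"
      rows[[length(rows) + 1L]] <- r
      r <- planted_row(rand_cdr3("CAL"), rand_cdr3("CASS"),
                       paste0(random_nonamers(1L), "V"))
      rows[[length(rows) + 1L]] <- r
      r <- planted_row(rand_cdr3("CAL"), rand_cdr3("CASS"),
                       random_nonamers(1L))
      r$allele <- "HLA-B*07:02"
      rows[[length(rows) + 1L]] <- r
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "planted_sets") <- planted_sets
    out
  })
}

#' Generate an activation assay with a planted distance dependence
#'
#' `readout = max(0, intercept + planted_slope * distance + noise)`:
#' activation falls off monotonically with distance from the reference, the
#' relationship the in-vitro variant assays exhibit.
#'
#' @param distances Named numeric vector of variant -> reference distances.
#' @param config A [synthetic_config()]; supplies slope, noise SD and seed.
#' @param intercept Baseline readout at distance 0.
#' @param clone_id Clone label carried on the rows.
#' @return Data.frame with `variant_id`, `clone_id`, `readout`.
#' @export
generate_activation_assay <- function(distances,
                                      config = synthetic_config(),
                                      intercept = NULL, clone_id = "clone1") {
  if (is.null(intercept)) {
    # keep readouts mostly positive under the planted slope
    intercept <- -config$planted_slope * max(distances) + 3 * config$noise_sd
  }
  with_seed(config$seed + 202L, {
    noise <- stats::rnorm(length(distances), 0, config$noise_sd)
    data.frame(
      variant_id = names(distances),
      clone_id = clone_id,
      readout = pmax(0, intercept + config$planted_slope * distances + noise),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate self, viral and tumor epitope pools
#'
#' Self and viral pools of unique anchor-compatible nonamers with an exact
#' planted overlap (`round(shared_fraction * n_self)` self sequences copied
#' into the viral pool); multiplicities follow geometric laws with the viral
#' pool less redundant than the self pool. Each tumor epitope is a
#' conservative one-residue variant of a parent drawn from the self pool
#' with probability `mimic_self_fraction`, otherwise from the viral pool —
#' the planted mimicry structure that closest-match classification should
#' recover.
#'
#' @param config A [synthetic_config()].
#' @return List with data.frames `self`, `viral` (columns `sequence`,
#'   `origin`, `multiplicity`) and `tumor` (columns `sequence`, `origin`,
#'   `planted_origin`, `parent`).
#' @export
generate_epitope_pools <- function(config = synthetic_config()) {
  n_shared <- round(config$shared_fraction * config$n_self)
  if (n_shared > min(config$n_self, config$n_viral)) {
    stop("pools too small for the requested overlap", call. = FALSE)
  }
  with_seed(config$seed + 303L, {
    grow_unique <- function(n, avoid = character(0)) {
      out <- character(0)
      while (length(out) < n) {
        out <- setdiff(unique(c(out, random_nonamers(n - length(out)))),
                       avoid)
      }
      out[seq_len(n)]
    }
    self_seq <- grow_unique(config$n_self)
    shared <- if (n_shared > 0) sample(self_seq, n_shared) else character(0)
    viral_seq <- c(shared,
                   grow_unique(config$n_viral - n_shared, avoid = self_seq))

    self <- data.frame(
      sequence = self_seq, origin = "SELF",
      multiplicity = 1L + stats::rgeom(config$n_self, 0.35),
      stringsAsFactors = FALSE
    )
    viral <- data.frame(
      sequence = viral_seq, origin = "VIRAL",
      multiplicity = 1L + stats::rgeom(config$n_viral, 0.65),
      stringsAsFactors = FALSE
    )

    parent_pool <- list(SELF = setdiff(self_seq, shared),
                        VIRAL = setdiff(viral_seq, shared))
    n_self_mimic <- round(config$mimic_self_fraction * config$n_tumor)
    planted <- sample(c(rep("SELF", n_self_mimic),
                        rep("VIRAL", config$n_tumor - n_self_mimic)))
    taken <- c(self_seq, viral_seq)
    tumor_seq <- character(config$n_tumor)
    parents <- character(config$n_tumor)
    for (i in seq_len(config$n_tumor)) {
      repeat {
        parent <- sample(parent_pool[[planted[i]]], 1L)
        for (pos in sample(c(4L, 5L, 6L, 8L))) {
          chars <- strsplit(parent, "")[[1]]
          chars[pos] <- CONSERVATIVE_SUB[[chars[pos]]]
          cand <- paste(chars, collapse = "")
          if (!cand %in% taken) break
        }
        if (!cand %in% taken) break
      }
      tumor_seq[i] <- cand
      parents[i] <- parent
      taken <- c(taken, cand)
    }
    tumor <- data.frame(
      sequence = tumor_seq, origin = "TUMOR", planted_origin = planted,
      parent = parents, stringsAsFactors = FALSE
    )
    list(self = self, viral = viral, tumor = tumor)
  })
}
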