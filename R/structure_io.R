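# Reading, annotating and aggregating per-atom pHLA structures.
#
# Structures arrive as PQR (whitespace-separated PDB2PQR dialect): per atom,
# its serial, name, residue, chain, residue number, XYZ, charge and radius.
# Downstream analysis never works at the atom level: atoms are averaged into
# one row per residue and the table is filtered to one of three scopes —
# the whole complex, its extracellular portion, or the epitope alone.

#' Parse a PQR structure file
#'
#' Reads whitespace-separated `ATOM`/`HETATM` records (the PDB2PQR dialect:
#' record, serial, atom name, residue name, chain, residue number, x, y, z,
#' charge, radius). All other lines (`REMARK`, `TER`, ...) are ignored.
#'
#' @param source Path to a PQR file, or a character vector of lines.
#' @return A `StructureTable`: a list with `atoms` (data.frame with columns
#'   `atom_index`, `atom_name`, `residue_name`, `chain_id`, `residue_number`,
#'   `x`, `y`, `z`, `charge`, `radius`, in file order) and `role_map`
#'   (`NULL` until [annotate_chains()] is called).
#' @seealso [write_pqr()], [annotate_chains()], [aggregate_residues()]
#' @export
parse_pqr <- function(source) {
  if (is.character(source) && length(source) == 1L && !grepl("\n", source) &&
      file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
  } else if (is.character(source)) {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  } else {
    stop("source must be a file path or character lines", call. = FALSE)
  }
  if (length(lines) == 0L) stop("empty PQR stream", call. = FALSE)

  is_atom <- grepl("^(ATOM|HETATM)\\b", lines)
  if (!any(is_atom)) stop("no ATOM/HETATM records in PQR stream", call. = FALSE)

  idx <- which(is_atom)
  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(fields) != 11L) {
      stop("malformed PQR atom line ", i, ": expected 11 whitespace-separated ",
           "fields, got ", length(fields), call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(fields[c(2, 6, 7, 8, 9, 10, 11)]))
    if (anyNA(num)) {
      stop("malformed PQR atom line ", i, ": non-numeric field", call. = FALSE)
    }
    rows[[k]] <- data.frame(
      atom_index = as.integer(num[1]),
      atom_name = fields[3],
      residue_name = fields[4],
      chain_id = fields[5],
      residue_number = as.integer(num[2]),
      x = num[3], y = num[4], z = num[5],
      charge = num[6], radius = num[7],
      stringsAsFactors = FALSE
    )
  }
  atoms <- do.call(rbind, rows)
  if (any(atoms$radius < 0)) stop("negative atom radius", call. = FALSE)
  if (any(atoms$residue_number < 1L)) {
    stop("residue_number must be >= 1", call. = FALSE)
  }
  structure(list(atoms = atoms, role_map = NULL), class = "StructureTable")
}

#' Write a structure back to PQR
#'
#' Inverse of [parse_pqr()] on the retained fields: coordinates are written
#' to 3 decimals, charge and radius to 4, so a parse/write round trip is the
#' identity at that precision.
#'
#' @param table A `StructureTable`.
#' @param path Output file path.
#' @export
write_pqr <- function(table, path) {
  stopifnot(inherits(table, "StructureTable"))
  a <- table$atoms
  if (is.null(a) || nrow(a) == 0L) stop("empty structure table", call. = FALSE)
  lines <- sprintf("ATOM %d %s %s %s %d %.3f %.3f %.3f %.4f %.4f",
                   a$atom_index, a$atom_name, a$residue_name, a$chain_id,
                   a$residue_number, a$x, a$y, a$z, a$charge, a$radius)
  writeLines(lines, path)
  invisible(path)
}

#' Assign chain roles (HLA, B2M, epitope)
#'
#' Explicit rules take precedence; otherwise a chain-length heuristic is
#' applied: the unique 9-residue chain is the epitope, the longest chain the
#' HLA heavy chain, and the remaining chain beta-2-microglobulin.
#'
#' @param table A `StructureTable`.
#' @param rules Optional named character vector, `chain_id -> role`
#'   with roles among `"HLA"`, `"B2M"`, `"EPITOPE"`.
#' @return The table with `role_map` populated. Exactly one chain must end
#'   up as the epitope.
#' @export
annotate_chains <- function(table, rules = NULL) {
  stopifnot(inherits(table, "StructureTable"))
  chains <- unique(table$atoms$chain_id)
  n_res <- vapply(chains, function(ch) {
    length(unique(table$atoms$residue_number[table$atoms$chain_id == ch]))
  }, integer(1))

  role_map <- setNames(rep(NA_character_, length(chains)), chains)
  if (!is.null(rules)) {
    bad <- setdiff(rules, CHAIN_ROLES)
    if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    known <- intersect(names(rules), chains)
    role_map[known] <- rules[known]
  }

  open <- names(role_map)[is.na(role_map)]
  if (length(open)) {
    nine <- open[n_res[open] == 9L]
    if (!"EPITOPE" %in% role_map) {
      if (length(nine) == 0L) {
        stop("no 9-residue chain and no explicit EPITOPE rule", call. = FALSE)
      }
      if (length(nine) > 1L) {
        stop("ambiguous epitope: chains ", paste(nine, collapse = ", "),
             " all have 9 residues; supply explicit rules", call. = FALSE)
      }
      role_map[nine] <- "EPITOPE"
    }
    open <- names(role_map)[is.na(role_map)]
    if (length(open)) {
      if (!"HLA" %in% role_map) {
        longest <- open[which.max(n_res[open])]
        role_map[longest] <- "HLA"
        open <- setdiff(open, longest)
      }
      role_map[open] <- "B2M"
    }
  }

  if (sum(role_map == "EPITOPE") != 1L) {
    stop("exactly one chain must have role EPITOPE", call. = FALSE)
  }
  epi <- names(role_map)[role_map == "EPITOPE"]
  if (n_res[epi] != 9L) {
    stop("epitope chain ", epi, " has ", n_res[epi],
         " residues; nonamers required", call. = FALSE)
  }
  table$role_map <- role_map
  table
}

#' Aggregate atoms to per-residue features
#'
#' Collapses each residue to a single row by unweighted arithmetic means of
#' charge, radius and coordinates over its atoms. Rows are ordered HLA, B2M,
#' EPITOPE and by residue number within each role.
#'
#' @param table An annotated `StructureTable`.
#' @return A data.frame with columns `role`, `residue_number`,
#'   `residue_name`, `x`, `y`, `z`, `charge`, `radius`.
#' @export
aggregate_residues <- function(table) {
  stopifnot(inherits(table, "StructureTable"))
  if (is.null(table$role_map)) {
    stop("structure not annotated; call annotate_chains() first", call. = FALSE)
  }
  a <- table$atoms
  a$role <- unname(table$role_map[a$chain_id])
  key <- interaction(a$role, a$residue_number, drop = TRUE)
  agg <- function(v) tapply(v, key, mean)
  first <- function(v) tapply(v, key, function(z) z[[1]])
  out <- data.frame(
    role = as.character(first(a$role)),
    residue_number = as.integer(first(a$residue_number)),
    residue_name = as.character(first(a$residue_name)),
    x = as.numeric(agg(a$x)), y = as.numeric(agg(a$y)),
    z = as.numeric(agg(a$z)),
    charge = as.numeric(agg(a$charge)),
    radius = as.numeric(agg(a$radius)),
    stringsAsFactors = FALSE
  )
  out <- out[order(match(out$role, CHAIN_ROLES), out$residue_number), ]
  rownames(out) <- NULL
  out
}

#' Filter a residue table to a structural scope
#'
#' `PHLA` keeps everything; `EC_PHLA` keeps the epitope plus HLA heavy-chain
#' residues numbered <= 180 (the extracellular portion), dropping B2M;
#' `EPITOPE` keeps the nine epitope rows.
#'
#' @param rows Residue feature data.frame from [aggregate_residues()].
#' @param scope One of `"PHLA"`, `"EC_PHLA"`, `"EPITOPE"`.
#' @export
apply_scope <- function(rows, scope) {
  if (!is.character(scope) || length(scope) != 1L || !scope %in% SCOPES) {
    stop("unknown scope: ", paste(scope, collapse = ","),
         " (expected one of ", paste(SCOPES, collapse = ", "), ")",
         call. = FALSE)
  }
  out <- switch(scope,
    PHLA = rows,
    EC_PHLA = rows[(rows$role == "EPITOPE") |
                     (rows$role == "HLA" & rows$residue_number <= 180L), ],
    EPITOPE = rows[rows$role == "EPITOPE", ]
  )
  rownames(out) <- NULL
  out
}

#' Write a residue feature table as TSV
#' @param rows Residue feature data.frame.
#' @param path Output path.
#' @export
write_residue_table <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a residue feature table written by [write_residue_table()]
#' @param path Input path.
#' @export
read_residue_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
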