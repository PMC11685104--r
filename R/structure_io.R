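# Reading and writing the formats the tool touches: PDB backbones,
# FASTA sequences and Vienna dot-bracket files.

#' Construct an RNA backbone structure object
#'
#' An `rna_backbone` holds one chain's nucleotides in 5'->3' order with the
#' 3D coordinates of the six backbone atoms P, O5', C5', C4', C3', O3' per
#' residue. Coordinates are in Angstrom, as stored in the source file.
#'
#' @param chain_id Chain identifier.
#' @param residue_number Integer vector of author residue numbers.
#' @param residue_name Character vector of residue names (e.g. "A", "PSU").
#' @param coords Numeric array `N x 6 x 3`; second dimension named with the
#'   six backbone atoms.
#' @param insert Insertion codes ("" when absent).
#' @param native_sequence Optional native sequence string over A/U/C/G/N.
#' @param segment Integer vector of contiguous-segment ids (chain breaks from
#'   dropped or missing residues increment the id); defaults to one segment.
#' @param n_dropped Number of residues dropped during parsing.
#' @return An object of class `rna_backbone`.
#' @export
new_rna_backbone <- function(chain_id, residue_number, residue_name, coords,
                             insert = NULL, native_sequence = NULL,
                             segment = NULL, n_dropped = 0L) {
  n <- length(residue_number)
  stopifnot(length(residue_name) == n,
            is.array(coords), all(dim(coords) == c(n, 6L, 3L)))
  if (is.null(dimnames(coords)[[2]])) dimnames(coords)[[2]] <- BACKBONE_ATOMS
  if (!all(is.finite(coords))) stop("backbone coordinates must be finite")
  structure(
    list(chain_id = chain_id,
         residue_number = as.integer(residue_number),
         insert = insert %||% rep("", n),
         residue_name = as.character(residue_name),
         coords = coords,
         native_sequence = native_sequence,
         segment = as.integer(segment %||% rep(1L, n)),
         n_dropped = as.integer(n_dropped)),
    class = "rna_backbone")
}

#' @export
length.rna_backbone <- function(x) length(x$residue_number)

#' @export
print.rna_backbone <- function(x, ...) {
  cat(sprintf("RNA backbone: chain %s, %d residues (%d dropped), %d segment(s)\n",
              x$chain_id, length(x), x$n_dropped, max(x$segment)))
  if (!is.null(x$native_sequence)) {
    cat("native sequence:", substr(x$native_sequence, 1, 60),
        if (nchar(x$native_sequence) > 60) "..." else "", "\n")
  }
  invisible(x)
}

# Documented mapping of common modified nucleotides to parent bases; anything
# not listed here and not A/U/C/G becomes "N".
MODIFIED_BASE_TABLE <- c(
  PSU = "U", "5MC" = "C", "5MU" = "U", "4SU" = "U", H2U = "U", OMU = "U",
  "1MA" = "A", "2MA" = "A", A2M = "A", MA6 = "A", "6MZ" = "A",
  OMC = "C", "4OC" = "C",
  "1MG" = "G", "2MG" = "G", M2G = "G", "7MG" = "G", OMG = "G", YG = "G",
  G7M = "G", QUO = "G")

#' Parse an RNA backbone chain from PDB text
#'
#' Reads ATOM/HETATM records of one chain and retains, per residue, the six
#' backbone atoms P, O5', C5', C4', C3', O3' (both the prime `'` and star `*`
#' atom-name dialects are accepted). Residues missing any of the six atoms
#' are dropped (and counted), not imputed; the resulting chain breaks are
#' recorded as segment boundaries and treated as termini downstream.
#' Alternate locations resolve to the highest occupancy (ties: first record);
#' only MODEL 1 of multi-model files is used; insertion codes are preserved
#' in the residue ordering.
#'
#' @param pdb_text PDB file content as a single string or character vector of
#'   lines (a path also works, but text is the primary interface).
#' @param chain_id Single chain identifier to extract.
#' @return An [new_rna_backbone()] object with `native_sequence` filled from
#'   the residue names via [extract_sequence()].
#' @export
parse_backbone <- function(pdb_text, chain_id) {
  stopifnot(length(chain_id) == 1L, nchar(chain_id) >= 1L)
  if (length(pdb_text) == 1L && !grepl("\n", pdb_text) && file.exists(pdb_text)) {
    path <- pdb_text
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(if (length(pdb_text) == 1L) strsplit(pdb_text, "\n")[[1]] else pdb_text,
               path)
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                          rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  at$chain[is.na(at$chain)] <- ""
  if (!any(at$chain == chain_id)) stop("chain not found: ", chain_id)
  at <- at[at$chain == chain_id, , drop = FALSE]
  # normalize the star dialect (O5*, C5*, ...) to primes
  at$elety <- gsub("*", "'", at$elety, fixed = TRUE)
  at <- at[at$elety %in% BACKBONE_ATOMS, , drop = FALSE]
  if (nrow(at) == 0L) stop("no usable backbone in chain ", chain_id)
  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1

  res_key <- paste(at$resno, at$insert, sep = "|")
  res_order <- unique(res_key)  # file order is the 5'->3' order
  kept <- list(); dropped <- 0L; break_before <- logical(0)
  prev_resno <- NULL; pending_break <- FALSE
  for (rk in res_order) {
    sub <- at[res_key == rk, , drop = FALSE]
    xyz <- matrix(NA_real_, 6L, 3L, dimnames = list(BACKBONE_ATOMS, NULL))
    for (atom in BACKBONE_ATOMS) {
      cand <- sub[sub$elety == atom, , drop = FALSE]
      if (nrow(cand) == 0L) next
      # altloc: highest occupancy wins, ties go to the first record
      cand <- cand[order(-cand$o), , drop = FALSE]
      xyz[atom, ] <- as.numeric(cand[1L, c("x", "y", "z")])
    }
    resno <- sub$resno[1L]
    if (anyNA(xyz) || !all(is.finite(xyz))) {
      dropped <- dropped + 1L
      pending_break <- TRUE
      next
    }
    gap <- !is.null(prev_resno) && (resno - prev_resno) > 1L
    kept[[length(kept) + 1L]] <- list(resno = resno, insert = sub$insert[1L],
                                      resid = sub$resid[1L], xyz = xyz)
    break_before <- c(break_before, pending_break || gap)
    pending_break <- FALSE
    prev_resno <- resno
  }
  if (length(kept) == 0L) stop("no usable backbone in chain ", chain_id)
  n <- length(kept)
  coords <- array(NA_real_, c(n, 6L, 3L), dimnames = list(NULL, BACKBONE_ATOMS, NULL))
  for (i in seq_len(n)) coords[i, , ] <- kept[[i]]$xyz
  segment <- cumsum(c(TRUE, break_before[-1L]))
  bb <- new_rna_backbone(
    chain_id = chain_id,
    residue_number = vapply(kept, `[[`, 0, "resno"),
    residue_name = trimws(vapply(kept, `[[`, "", "resid")),
    coords = coords,
    insert = vapply(kept, `[[`, "", "insert"),
    segment = segment,
    n_dropped = dropped)
  bb$native_sequence <- extract_sequence(bb)
  bb
}

#' Extract the nucleotide sequence from a backbone structure
#'
#' Residue names A/U/C/G map to themselves; a documented modified-base table
#' (e.g. PSU -> U, 5MC -> C) handles common modified nucleotides; anything
#' else becomes the policy token "N".
#'
#' @param structure An `rna_backbone`.
#' @return A single string over A/U/C/G/N.
#' @export
extract_sequence <- function(structure) {
  stopifnot(inherits(structure, "rna_backbone"), length(structure) > 0L)
  nm <- toupper(structure$residue_name)
  out <- ifelse(nm %in% NUCLEOTIDES, nm,
                ifelse(nm %in% names(MODIFIED_BASE_TABLE),
                       MODIFIED_BASE_TABLE[nm], "N"))
  paste(out, collapse = "")
}

#' Parse a Vienna dot-bracket secondary structure
#'
#' Accepts a bare structure string or a Vienna-style record (optional `>`
#' header line, optional sequence line, then the structure line). The
#' alphabet is exactly `.`, `(`, `)`: pseudoknot annotations written with
#' other bracket types (`[]`, `{}`, `<>`) or letters are remapped to `.`
#' with a warning. Unbalanced parentheses are an error.
#'
#' @param text Character scalar or vector of lines.
#' @return An object of class `rna_ss`: a list with `symbols` (string) and
#'   `length`.
#' @export
parse_dot_bracket <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n")[[1]] else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lines <- lines[!startsWith(lines, ">")]
  is_seq <- grepl("^[ACGUTNacgutn]+$", lines)
  struct_lines <- lines[!is_seq]
  if (length(struct_lines) == 0L) stop("no structure line found")
  s <- sub("\\s.*$", "", struct_lines[[1L]])  # strip trailing energy etc.
  chars <- strsplit(s, "")[[1]]
  knot <- grepl("^[][{}<>A-Za-z]$", chars)
  if (any(knot)) {
    warning(sprintf("remapped %d pseudoknot/non-standard symbols to '.'",
                    sum(knot)))
    chars[knot] <- "."
  }
  if (!all(chars %in% SS_SYMBOLS)) {
    stop("illegal character in secondary structure: ",
         paste(unique(chars[!chars %in% SS_SYMBOLS]), collapse = ""))
  }
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0L) || depth[length(depth)] != 0L) {
    stop("invalid secondary structure: unbalanced parentheses")
  }
  new_rna_ss(paste(chars, collapse = ""))
}

#' @rdname parse_dot_bracket
#' @param symbols A string over `.`, `(`, `)` (already balanced).
#' @export
new_rna_ss <- function(symbols) {
  structure(list(symbols = symbols, length = nchar(symbols)), class = "rna_ss")
}

#' @export
print.rna_ss <- function(x, ...) {
  cat(sprintf("Secondary structure (%d nt): %s\n", x$length, x$symbols))
  invisible(x)
}

#' Write sequences to a FASTA file
#'
#' Standard FASTA with 60-column line wrapping, via Biostrings.
#'
#' @param records Named character vector or named list of sequence strings.
#' @param destination Output file path.
#' @export
write_fasta <- function(records, destination) {
  records <- unlist(records)
  if (length(records) == 0L) stop("no records")
  if (is.null(names(records)) || any(!nzchar(names(records)))) {
    stop("all records need ids")
  }
  set <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(set, destination, width = 60L)
  invisible(NULL)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write a backbone structure to a PDB file
#'
#' Serializes the six backbone atoms per residue as ATOM records (prime
#' dialect atom names), so generated fixtures double as format-conformance
#' inputs for [parse_backbone()].
#'
#' @param structure An `rna_backbone`.
#' @param path Output file path.
#' @export
write_backbone_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "rna_backbone"))
  n <- length(structure)
  xyz <- matrix(aperm(structure$coords, c(3L, 2L, 1L)), nrow = 1L)  # x1,y1,z1,...
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(xyz),
    type = rep("ATOM", n * 6L),
    resno = rep(structure$residue_number, each = 6L),
    resid = rep(structure$residue_name, each = 6L),
    eleno = seq_len(n * 6L),
    elety = rep(BACKBONE_ATOMS, n),
    chain = rep(structure$chain_id, n * 6L),
    insert = rep(structure$insert, each = 6L),
    o = rep(1, n * 6L),
    b = rep(0, n * 6L))
  invisible(NULL)
}

#' Write a dot-bracket file
#'
#' @param ss An `rna_ss` or dot-bracket string.
#' @param path Output file path.
#' @param id Optional record id written as a `>` header.
#' @param sequence Optional sequence line.
#' @export
write_dot_bracket <- function(ss, path, id = NULL, sequence = NULL) {
  symbols <- if (inherits(ss, "rna_ss")) ss$symbols else ss
  lines <- character(0)
  if (!is.null(id)) lines <- c(lines, paste0(">", id))
  if (!is.null(sequence)) lines <- c(lines, sequence)
  writeLines(c(lines, symbols), path)
  invisible(NULL)
}
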