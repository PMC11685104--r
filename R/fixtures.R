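# Synthetic-data generation: parametric helical backbones, seeded
# perturbations, and toy datasets whose sequence is a deterministic function
# of local geometry (so structure->sequence learning is possible without any
# downloaded data).

# Default local offsets (Angstrom) of the five non-P backbone atoms relative
# to P, expressed in the helical frame (radial, tangential, axial). Chosen so
# successive along-chain atom distances are bond-like (1.2-1.5 A) and all
# intra-residue pairs fall in (0.5, 5) A; no biological-accuracy claim.
DEFAULT_ATOM_OFFSETS <- matrix(
  c(1.2,  0.9, 0.2,
    2.2,  1.5, 0.8,
    3.2,  1.2, 1.5,
    3.9,  0.1, 2.0,
    4.3, -1.2, 1.8),
  nrow = 5L, byrow = TRUE,
  dimnames = list(c("O5'", "C5'", "C4'", "C3'", "O3'"), NULL))

#' Helix fixture parameters
#'
#' Geometry of the synthetic backbone helix. Defaults approximate the scale
#' of A-form RNA (rise 2.8 A, twist 32.7 degrees, radius 9.4 A gives
#' successive P-P distances of about 6 A) without claiming biological
#' accuracy.
#'
#' @param rise_per_residue Axial rise per residue (Angstrom).
#' @param twist_per_residue Rotation per residue (degrees); may be a vector
#'   (recycled) for non-uniform helices.
#' @param radius Helix radius (Angstrom).
#' @param atom_offsets 5 x 3 matrix of local offsets of O5', C5', C4', C3',
#'   O3' relative to P in the (radial, tangential, axial) frame.
#' @return A list of class `helix_params`.
#' @export
helix_params <- function(rise_per_residue = 2.8, twist_per_residue = 32.7,
                         radius = 9.4, atom_offsets = DEFAULT_ATOM_OFFSETS) {
  stopifnot(all(rise_per_residue > 0), radius > 0,
            is.matrix(atom_offsets), nrow(atom_offsets) == 5L,
            ncol(atom_offsets) == 3L)
  d <- sqrt(rowSums(atom_offsets^2))
  if (any(d <= 0.5) || any(d >= 5)) {
    stop("atom offsets must give inter-atom distances in (0.5, 5) Angstrom")
  }
  structure(list(rise_per_residue = rise_per_residue,
                 twist_per_residue = twist_per_residue,
                 radius = radius, atom_offsets = atom_offsets),
            class = "helix_params")
}

#' Generate a synthetic helical RNA backbone
#'
#' P atoms lie on a regular (or per-residue-twist) helix; the five other
#' backbone atoms are placed by rotating fixed local offsets with the helical
#' frame at each residue. Deterministic: no randomness.
#'
#' @param n Number of residues (>= 3).
#' @param params A [helix_params()] object.
#' @param sequence Optional sequence string of length `n` used as residue
#'   names; default all "A".
#' @param offset_rotation Optional per-residue rotation (degrees, length `n`)
#'   of the atom offsets about the helix axis, used by [toy_dataset()] to
#'   imprint a per-residue geometric signature.
#' @param chain_id Chain identifier for the resulting structure.
#' @return An `rna_backbone`.
#' @export
synth_helix <- function(n, params = helix_params(), sequence = NULL,
                        offset_rotation = NULL, chain_id = "A") {
  if (n < 3L) stop("n must be at least 3")
  twist <- rep_len(params$twist_per_residue, n) * pi / 180
  ang <- cumsum(c(0, twist[-n]))
  rot_deg <- rep_len(offset_rotation %||% 0, n) * pi / 180
  r <- params$radius
  coords <- array(NA_real_, c(n, 6L, 3L),
                  dimnames = list(NULL, BACKBONE_ATOMS, NULL))
  for (i in seq_len(n)) {
    a <- ang[i]
    p <- c(r * cos(a), r * sin(a), (i - 1L) * params$rise_per_residue)
    e_r <- c(cos(a), sin(a), 0)
    e_t <- c(-sin(a), cos(a), 0)
    e_z <- c(0, 0, 1)
    frame <- cbind(e_r, e_t, e_z)
    cr <- cos(rot_deg[i]); sr <- sin(rot_deg[i])
    spin <- matrix(c(cr, sr, 0, -sr, cr, 0, 0, 0, 1), 3L, 3L)
    coords[i, "P", ] <- p
    off <- params$atom_offsets %*% t(spin)   # rotate offsets about local axis
    coords[i, 2:6, ] <- rep(p, each = 5L) + off %*% t(frame)
  }
  seq_chr <- if (is.null(sequence)) strrep("A", n) else sequence
  stopifnot(nchar(seq_chr) == n)
  new_rna_backbone(chain_id = chain_id, residue_number = seq_len(n),
                   residue_name = strsplit(seq_chr, "")[[1]],
                   coords = coords, native_sequence = seq_chr)
}

#' Perturb a backbone with isotropic Gaussian noise
#'
#' @param structure An `rna_backbone`.
#' @param sigma Noise standard deviation per coordinate (Angstrom, >= 0).
#'   `sigma = 0` returns the structure unchanged.
#' @param seed Integer seed; the perturbation is a pure function of
#'   (structure, sigma, seed).
#' @return A perturbed `rna_backbone`.
#' @export
perturb <- function(structure, sigma, seed = 1L) {
  stopifnot(inherits(structure, "rna_backbone"), sigma >= 0)
  if (sigma == 0) return(structure)
  noise <- with_seed(seed, array(stats::rnorm(length(structure$coords),
                                              sd = sigma),
                                 dim = dim(structure$coords)))
  out <- structure
  out$coords <- structure$coords + noise
  out
}

# Twist bins (degrees) and offset-spin bins (degrees) that encode each
# nucleotide class in the toy geometry, in distribution column order A,U,C,G.
TOY_TWIST_BINS <- c(A = 30, U = 32.5, C = 35, G = 37.5)
TOY_SPIN_BINS <- c(A = -12, U = -4, C = 4, G = 12)

#' Generate a toy structure->sequence dataset
#'
#' Each item is a perturbed helix whose per-residue geometry carries its
#' nucleotide label: residue `i`'s label sets both the helical twist of the
#' step leaving it and a small rotation of its own atom offsets, so the label
#' is recoverable from the intra- and inter-nucleotide features of the
#' structure graph. The secondary structure is a simple hairpin consistent
#' with the length. Generation is a pure function of its arguments.
#'
#' @param num Number of items (>= 1).
#' @param length_range Length range `c(min, max)`, within 10..500 (the model
#'   targets chains up to 500 nucleotides).
#' @param seed Integer seed.
#' @param sigma Coordinate noise in Angstrom (default 0.1).
#' @return A list of items, each `list(structure, sequence, secondary)`.
#' @export
toy_dataset <- function(num, length_range = c(30L, 60L), seed = 1L,
                        sigma = 0.1) {
  stopifnot(num >= 1L, length(length_range) == 2L)
  lo <- length_range[1L]; hi <- length_range[2L]
  if (!(10L <= lo && lo <= hi && hi <= 500L)) stop("invalid length range")
  with_seed(seed, {
    lapply(seq_len(num), function(item) {
      n <- if (lo == hi) lo else sample(lo:hi, 1L)
      labels <- sample(NUCLEOTIDES, n, replace = TRUE)
      twists <- TOY_TWIST_BINS[labels]
      spins <- TOY_SPIN_BINS[labels]
      st <- synth_helix(n, helix_params(twist_per_residue = unname(twists),
                                        radius = 9.2),
                        sequence = paste(labels, collapse = ""),
                        offset_rotation = unname(spins))
      st <- perturb(st, sigma, seed = sample.int(2^31 - 1L, 1L))
      k <- max(0L, (n - 3L) %/% 2L)
      ss <- new_rna_ss(paste0(strrep("(", k), strrep(".", n - 2L * k),
                              strrep(")", k)))
      list(structure = st, sequence = st$native_sequence, secondary = ss)
    })
  })
}
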