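# Shared fixture builders for the test suite.

# A non-degenerate backbone: perturbed helix so distances carry no exact
# ties (regular helices have screw symmetry and hence tied distances).
random_backbone <- function(n, seed, sigma = 0.3) {
  perturb(synth_helix(n), sigma, seed = seed)
}

# Small configurations keep network tests fast.
tiny_graph_config <- function() graph_config(K = 5, rbf_count = 6)

tiny_model_config <- function(seed = 1L, iterations = 2L) {
  model_config(encoder_layers = 2L, hidden_dim = 16L, ss_head_heads = 2L,
               refinement_iterations = iterations, dropout = 0,
               prior_embed_dim = 4L, seed = seed)
}

tiny_model <- function(seed = 1L, iterations = 2L) {
  init_model(tiny_model_config(seed, iterations), tiny_graph_config())
}

# Hand-written PDB fixture text: `residues` is a list of lists with fields
# resno, resid, atoms (named list atom -> xyz), optionally chain.
make_pdb_text <- function(residues, chain = "A") {
  lines <- character(0)
  eleno <- 0L
  for (r in residues) {
    for (atom in names(r$atoms)) {
      eleno <- eleno + 1L
      xyz <- r$atoms[[atom]]
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
        eleno, atom, r$resid, r$chain %||% chain, r$resno,
        xyz[1], xyz[2], xyz[3], r$occ %||% 1.0, 0.0))
    }
  }
  paste(c(lines, "END"), collapse = "\n")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Residue helper with all six atoms placed at small offsets around `origin`.
full_residue <- function(resno, origin, resid = "A") {
  offs <- list(
    "P" = c(0, 0, 0), "O5'" = c(1.2, 0.3, 0.2), "C5'" = c(2.1, 1.0, 0.6),
    "C4'" = c(3.0, 0.8, 1.4), "C3'" = c(3.6, -0.4, 1.9),
    "O3'" = c(4.1, -1.5, 1.5))
  atoms <- lapply(offs, function(o) origin + o)
  list(resno = resno, resid = resid, atoms = atoms)
}
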