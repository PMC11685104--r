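# Three-level evaluation of designed sequences: sequence metrics (recovery,
# Macro-F1), secondary-structure metrics (dot-bracket accuracy and
# recovered-sequence rate via pluggable folding backends), and the tertiary
# utility metric (superposed RMSD).

as_seq_chars <- function(x) {
  if (inherits(x, "rna_ss")) x <- x$symbols
  strsplit(x, "")[[1]]
}

#' Sequence recovery rate
#'
#' Percentage of positions at which the designed sequence exactly matches
#' the native sequence.
#'
#' @param designed,native Equal-length sequence strings.
#' @return Percentage in \[0, 100\].
#' @export
recovery_rate <- function(designed, native) {
  a <- as_seq_chars(designed); b <- as_seq_chars(native)
  if (length(a) != length(b)) stop("sequence length mismatch")
  100 * mean(a == b)
}

#' Macro-F1 score of designed sequences (x100)
#'
#' Per-nucleotide-class F1 scores averaged without class weighting, scaled
#' by 100. By default positions are pooled across all pairs and the
#' confusion matrix is global; classes with zero true and zero predicted
#' occurrences are excluded from the macro average, while classes with
#' support but no true positives contribute F1 = 0. `per_sample = TRUE`
#' instead computes a macro-F1 per pair and averages those.
#'
#' @param designed,native Character vectors (or single strings) of paired
#'   equal-length sequences.
#' @param per_sample Average per-pair macro-F1 instead of pooling.
#' @return Score in \[0, 100\].
#' @export
macro_f1 <- function(designed, native, per_sample = FALSE) {
  designed <- unlist(designed); native <- unlist(native)
  if (length(designed) == 0L) stop("empty input")
  if (length(designed) != length(native)) stop("paired inputs required")
  one <- function(pred, truth) {
    f1s <- vapply(NUCLEOTIDES, function(cl) {
      tp <- sum(pred == cl & truth == cl)
      fp <- sum(pred == cl & truth != cl)
      fn <- sum(pred != cl & truth == cl)
      if (tp + fp + fn == 0L) return(NA_real_)  # absent class: excluded
      if (tp == 0L) return(0)
      prec <- tp / (tp + fp); rec <- tp / (tp + fn)
      2 * prec * rec / (prec + rec)
    }, 0)
    100 * mean(f1s, na.rm = TRUE)
  }
  chars <- lapply(seq_along(designed), function(i) {
    a <- as_seq_chars(designed[i]); b <- as_seq_chars(native[i])
    if (length(a) != length(b)) stop("sequence length mismatch in pair ", i)
    list(a, b)
  })
  if (per_sample) {
    mean(vapply(chars, function(p) one(p[[1]], p[[2]]), 0))
  } else {
    one(unlist(lapply(chars, `[[`, 1L)), unlist(lapply(chars, `[[`, 2L)))
  }
}

#' Secondary-structure accuracy
#'
#' Position-wise percentage of matching symbols over the three-symbol
#' dot-bracket alphabet.
#'
#' @param predicted,truth Equal-length dot-bracket strings or `rna_ss`.
#' @return Percentage in \[0, 100\].
#' @export
ss_accuracy <- function(predicted, truth) {
  a <- as_seq_chars(predicted); b <- as_seq_chars(truth)
  if (length(a) != length(b)) stop("secondary structure length mismatch")
  100 * mean(a == b)
}

#' Recovered sequence rate
#'
#' Percentage of designed sequences a folding backend successfully folded.
#' A backend failure, timeout or length-mismatched return counts as failure.
#'
#' @param fold_outcomes Logical vector (TRUE = successfully folded).
#' @return Percentage in \[0, 100\].
#' @export
recovered_sequence_rate <- function(fold_outcomes) {
  if (length(fold_outcomes) == 0L) stop("empty outcome list")
  100 * mean(as.logical(fold_outcomes))
}

#' Root-mean-square deviation between point sets
#'
#' With `superpose = TRUE` (default) the second set is first optimally
#' superposed onto the first by rigid-body least squares (Kabsch algorithm
#' via SVD, reflections excluded), which requires at least 3 points.
#'
#' @param coords_a,coords_b N x 3 coordinate matrices (Angstrom).
#' @param superpose Apply optimal rigid superposition first.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(coords_a, coords_b, superpose = TRUE) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (!all(dim(a) == dim(b))) stop("coordinate count mismatch")
  n <- nrow(a)
  if (n < 1L) stop("need at least one point")
  if (superpose) {
    if (n < 3L) stop("superposition needs at least 3 points")
    ca <- colMeans(a); cb <- colMeans(b)
    A <- sweep(a, 2L, ca); B <- sweep(b, 2L, cb)
    H <- crossprod(B, A)
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    b <- sweep(B %*% t(R), 2L, ca, `+`)
    a <- a
  }
  sqrt(mean(rowSums((a - b)^2)))
}

#' Folding backends
#'
#' A fold backend is a list with a `name` and a `fold(sequence)` function
#' returning a dot-bracket string of the same length, or `NA` on failure.
#' `stub_fold_backend()` is a deterministic offline backend used for
#' testing: it returns the hairpin pattern matching the sequence length
#' (`mode = "hairpin"`), an all-unpaired string (`"dots"`), or always fails
#' (`"fail"`). `vienna_fold_backend()` wraps the RNAfold program of the
#' ViennaRNA suite when it is on the PATH; minimum-free-energy structures
#' are computed per sequence.
#'
#' @param mode Stub behaviour: "hairpin", "dots" or "fail".
#' @return A fold backend list.
#' @export
stub_fold_backend <- function(mode = "hairpin") {
  stopifnot(mode %in% c("hairpin", "dots", "fail"))
  list(name = paste0("stub-", mode), fold = function(sequence) {
    n <- nchar(sequence)
    switch(mode,
           fail = NA_character_,
           dots = strrep(".", n),
           hairpin = {
             k <- max(0L, (n - 3L) %/% 2L)
             paste0(strrep("(", k), strrep(".", n - 2L * k), strrep(")", k))
           })
  })
}

#' @rdname stub_fold_backend
#' @param rnafold Path to the RNAfold executable.
#' @export
vienna_fold_backend <- function(rnafold = "RNAfold") {
  if (!nzchar(Sys.which(rnafold))) stop("RNAfold not found on PATH")
  list(name = "vienna", fold = function(sequence) {
    out <- tryCatch(
      suppressWarnings(system2(rnafold, args = c("--noPS"),
                               input = sequence, stdout = TRUE,
                               stderr = FALSE)),
      error = function(e) character(0))
    if (length(out) < 2L) return(NA_character_)
    db <- sub("\\s.*$", "", out[[2L]])
    if (nchar(db) != nchar(sequence) ||
        !grepl("^[.()]+$", db)) return(NA_character_)
    db
  })
}

length_bin <- function(n) {
  cut(n, breaks = c(-Inf, 50, 100, Inf), right = FALSE,
      labels = c("Short", "Medium", "Long"))
}

#' Evaluate designed sequences against references
#'
#' Aggregates the three-level protocol over a set of designs: per-item and
#' aggregate sequence metrics (recovery; pooled Macro-F1), and - when a
#' folding backend is supplied - secondary-structure metrics (dot-bracket
#' accuracy of the folded designed sequence against the supplied truth, and
#' the recovered-sequence rate). Aggregates are also stratified by the
#' length bins Short \[0, 50), Medium \[50, 100), Long \[100, Inf).
#'
#' @param results List of `design_result` objects (or plain sequence
#'   strings).
#' @param references List of `list(sequence, secondary)` aligned with
#'   `results`; `secondary` may be NULL when no backend is used.
#' @param backend Optional fold backend (see [stub_fold_backend()]).
#' @return Object of class `design_report`: list with `per_item`
#'   (data.frame), `aggregate` and `by_bin` (data.frame), JSON-serializable.
#' @export
evaluate_design <- function(results, references, backend = NULL) {
  if (length(results) != length(references)) stop("misaligned lists")
  if (length(results) == 0L) stop("empty input")
  designed <- vapply(results, function(r) {
    if (inherits(r, "design_result")) r$sequence else as.character(r)
  }, "")
  native <- vapply(references, function(r) r$sequence, "")
  n_items <- length(designed)
  lens <- nchar(designed)
  per_item <- data.frame(
    item = seq_len(n_items),
    length = lens,
    bin = as.character(length_bin(lens)),
    recovery_pct = vapply(seq_len(n_items), function(i) {
      recovery_rate(designed[i], native[i])
    }, 0),
    stringsAsFactors = FALSE)

  fold_ok <- NULL
  if (!is.null(backend)) {
    per_item$ss_accuracy_pct <- NA_real_
    fold_ok <- logical(n_items)
    for (i in seq_len(n_items)) {
      db <- backend$fold(designed[i])
      ok <- !is.na(db) && nchar(db) == lens[i]
      fold_ok[i] <- ok
      truth <- references[[i]]$secondary
      if (ok && !is.null(truth)) {
        per_item$ss_accuracy_pct[i] <- ss_accuracy(db, truth)
      }
    }
  }

  aggregate <- list(
    n = n_items,
    recovery_pct = mean(per_item$recovery_pct),
    macro_f1_x100 = macro_f1(designed, native))
  if (!is.null(backend)) {
    aggregate$recovered_sequence_rate_pct <- recovered_sequence_rate(fold_ok)
    acc <- per_item$ss_accuracy_pct[!is.na(per_item$ss_accuracy_pct)]
    if (length(acc) > 0L) aggregate$ss_accuracy_pct <- mean(acc)
  }

  by_bin <- do.call(rbind, lapply(c("Short", "Medium", "Long"), function(b) {
    sel <- per_item$bin == b
    if (!any(sel)) return(NULL)
    data.frame(bin = b, n = sum(sel),
               recovery_pct = mean(per_item$recovery_pct[sel]),
               macro_f1_x100 = macro_f1(designed[sel], native[sel]),
               stringsAsFactors = FALSE)
  }))

  structure(list(per_item = per_item, aggregate = aggregate,
                 by_bin = by_bin,
                 backend = if (is.null(backend)) NULL else backend$name),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("Design evaluation over %d item(s)%s\n", x$aggregate$n,
              if (is.null(x$backend)) "" else
                sprintf(" (fold backend: %s)", x$backend)))
  cat(sprintf("  recovery: %.2f%%   macro-F1 (x100): %.2f\n",
              x$aggregate$recovery_pct, x$aggregate$macro_f1_x100))
  if (!is.null(x$aggregate$recovered_sequence_rate_pct)) {
    cat(sprintf("  recovered-sequence rate: %.1f%%",
                x$aggregate$recovered_sequence_rate_pct))
    if (!is.null(x$aggregate$ss_accuracy_pct)) {
      cat(sprintf("   secondary-structure accuracy: %.2f%%",
                  x$aggregate$ss_accuracy_pct))
    }
    cat("\n")
  }
  invisible(x)
}
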