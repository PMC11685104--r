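# Command-line entry points tying the pipeline together:
# structure in -> design -> evaluate -> report. Each command writes a run
# manifest sufficient to re-run it bit-identically on one platform, logs
# diagnostics to stderr, and returns a process exit code (0 success,
# 1 failure) rather than throwing.

write_run_manifest <- function(path, command, inputs, outputs, seed,
                               config = NULL) {
  manifest <- list(command = command,
                   tool = "rnadesign",
                   version = as.character(utils::packageVersion("rnadesign")),
                   seed = seed,
                   inputs = inputs,
                   outputs = outputs,
                   config = config,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

fail_cmd <- function(e) {
  message("error: ", conditionMessage(e))
  invisible(1L)
}

#' Design a sequence for a PDB backbone (CLI operation)
#'
#' Reads one chain from a PDB file, designs a sequence with the model in
#' `checkpoint`, and writes: `<out_prefix>.fasta` (designed sequence),
#' `<out_prefix>_iterations.tsv` (per-iteration per-position probability
#' table), `<out_prefix>.dbn` (predicted dot-bracket),
#' `<out_prefix>_metrics.json` (sequence metrics versus the native sequence
#' when one is available) and `<out_prefix>_manifest.json`.
#'
#' @param pdb_path Input PDB file.
#' @param chain Chain identifier.
#' @param checkpoint Checkpoint file from [save_checkpoint()].
#' @param out_prefix Output path prefix.
#' @param seed Seed (used in sampling mode).
#' @param iterations Optional override of the refinement iteration count.
#' @param mode `"argmax"` or `"sample"`.
#' @return Invisible exit code: 0 on success, 1 on failure.
#' @export
cmd_design <- function(pdb_path, chain, checkpoint, out_prefix,
                       seed = 1L, iterations = NULL, mode = "argmax") {
  tryCatch({
    model <- load_checkpoint(checkpoint)
    bb <- parse_backbone(pdb_path, chain)
    res <- design(bb, model, iterations = iterations, mode = mode,
                  seed = seed)
    id <- sprintf("%s_%s_designed", sub("\\.pdb$", "", basename(pdb_path)),
                  chain)
    fasta <- paste0(out_prefix, ".fasta")
    seqs <- stats::setNames(res$sequence, id)
    write_fasta(seqs, fasta)
    iter_tab <- do.call(rbind, lapply(seq_along(res$per_iteration),
                                      function(k) {
      P <- res$per_iteration[[k]]
      data.frame(iteration = k, position = seq_len(nrow(P)),
                 A = P[, "A"], U = P[, "U"], C = P[, "C"], G = P[, "G"])
    }))
    tsv <- paste0(out_prefix, "_iterations.tsv")
    utils::write.table(iter_tab, tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    dbn <- paste0(out_prefix, ".dbn")
    write_dot_bracket(res$predicted_dotbracket, dbn, id = id,
                      sequence = res$sequence)
    outputs <- list(fasta = fasta, iterations = tsv, dotbracket = dbn)
    native <- bb$native_sequence
    if (!is.null(native) && !grepl("N", native, fixed = TRUE)) {
      metrics <- list(recovery_pct = recovery_rate(res$sequence, native),
                      macro_f1_x100 = macro_f1(res$sequence, native),
                      length = res$n)
      mpath <- paste0(out_prefix, "_metrics.json")
      jsonlite::write_json(metrics, mpath, auto_unbox = TRUE, digits = NA)
      outputs$metrics <- mpath
    }
    write_run_manifest(paste0(out_prefix, "_manifest.json"), "design",
                       list(pdb = pdb_path, chain = chain,
                            checkpoint = checkpoint),
                       outputs, seed,
                       config = list(iterations = iterations, mode = mode))
    invisible(0L)
  }, error = fail_cmd)
}

#' Train a model from a dataset manifest (CLI operation)
#'
#' The manifest is a TSV with columns `pdb_path`, `chain`,
#' `dotbracket_path` (the last may be empty); the config is a YAML file
#' with optional `model`, `train` and `graph` sections whose entries
#' override [model_config()], [train_config()] and [graph_config()]
#' defaults. Writes `checkpoint.rds`, `training_log.jsonl` (one JSON record
#' per epoch) and `run_manifest.json` into `out_dir`.
#'
#' @param manifest_path Dataset manifest TSV.
#' @param config_path YAML configuration file (optional; NULL for defaults).
#' @param out_dir Output directory (created if needed).
#' @return Invisible exit code: 0 on success, 1 on failure.
#' @export
cmd_train <- function(manifest_path, config_path = NULL, out_dir) {
  tryCatch({
    man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
    if (nrow(man) == 0L) stop("empty dataset manifest")
    stopifnot(all(c("pdb_path", "chain") %in% names(man)))
    cfg <- if (!is.null(config_path)) yaml::read_yaml(config_path) else list()
    mc <- do.call(model_config, cfg$model %||% list())
    tc <- do.call(train_config, cfg$train %||% list())
    gc_ <- do.call(graph_config, cfg$graph %||% list())
    base_dir <- dirname(manifest_path)
    resolve <- function(p) {
      ifelse(file.exists(p), p, file.path(base_dir, p))
    }
    dataset <- lapply(seq_len(nrow(man)), function(i) {
      bb <- parse_backbone(resolve(man$pdb_path[i]), man$chain[i])
      ss <- NULL
      dbp <- if ("dotbracket_path" %in% names(man)) man$dotbracket_path[i]
      if (!is.null(dbp) && !is.na(dbp) && nzchar(dbp)) {
        ss <- parse_dot_bracket(readLines(resolve(dbp)))
      }
      list(structure = bb, sequence = bb$native_sequence, secondary = ss)
    })
    fit <- train(dataset, model_config = mc, train_config = tc,
                 graph_config = gc_)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ckpt <- file.path(out_dir, "checkpoint.rds")
    save_checkpoint(fit$model, ckpt)
    log_path <- file.path(out_dir, "training_log.jsonl")
    writeLines(vapply(seq_len(nrow(fit$record)), function(i) {
      jsonlite::toJSON(as.list(fit$record[i, ]), auto_unbox = TRUE,
                       digits = NA)
    }, ""), log_path)
    write_run_manifest(file.path(out_dir, "run_manifest.json"), "train",
                       list(manifest = manifest_path,
                            config = config_path),
                       list(checkpoint = ckpt, log = log_path),
                       tc$seed, config = cfg)
    invisible(0L)
  }, error = fail_cmd)
}

#' Evaluate designed against native sequences (CLI operation)
#'
#' Reads two FASTA files with matching record ids, optionally a truth
#' database of dot-bracket structures (TSV: `id`, `dotbracket`), and writes
#' a JSON report plus a per-item TSV with Short/Medium/Long length
#' stratification.
#'
#' @param designed_fasta,native_fasta FASTA paths with aligned record ids.
#' @param truth_db_path Optional dot-bracket truth TSV.
#' @param out_prefix Output path prefix.
#' @param backend `"stub"`, `"vienna"`, or `"none"`.
#' @return Invisible exit code: 0 on success, 1 on failure.
#' @export
cmd_eval <- function(designed_fasta, native_fasta, truth_db_path = NULL,
                     out_prefix = "eval", backend = "none") {
  tryCatch({
    des <- read_fasta(designed_fasta)
    nat <- read_fasta(native_fasta)
    missing_ids <- union(setdiff(names(des), names(nat)),
                         setdiff(names(nat), names(des)))
    if (length(missing_ids) > 0L) {
      stop("record id mismatch between files: ",
           paste(missing_ids, collapse = ", "))
    }
    nat <- nat[names(des)]
    truths <- stats::setNames(vector("list", length(des)), names(des))
    if (!is.null(truth_db_path)) {
      db <- utils::read.delim(truth_db_path, stringsAsFactors = FALSE)
      stopifnot(all(c("id", "dotbracket") %in% names(db)))
      for (i in seq_len(nrow(db))) {
        if (db$id[i] %in% names(truths)) {
          truths[[db$id[i]]] <- new_rna_ss(db$dotbracket[i])
        }
      }
    }
    be <- switch(backend,
                 none = NULL,
                 stub = stub_fold_backend(),
                 vienna = vienna_fold_backend(),
                 stop("unknown backend: ", backend))
    refs <- lapply(names(des), function(id) {
      list(sequence = unname(nat[[id]]), secondary = truths[[id]])
    })
    report <- evaluate_design(as.list(unname(des)), refs, backend = be)
    report$per_item$id <- names(des)
    json_path <- paste0(out_prefix, "_report.json")
    jsonlite::write_json(
      list(schema = "rnadesign-eval/1", aggregate = report$aggregate,
           by_bin = report$by_bin, per_item = report$per_item),
      json_path, auto_unbox = TRUE, digits = NA, null = "null")
    tsv_path <- paste0(out_prefix, "_per_item.tsv")
    utils::write.table(report$per_item, tsv_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    write_run_manifest(paste0(out_prefix, "_manifest.json"), "eval",
                       list(designed = designed_fasta, native = native_fasta,
                            truth_db = truth_db_path),
                       list(report = json_path, per_item = tsv_path),
                       seed = NA, config = list(backend = backend))
    invisible(0L)
  }, error = fail_cmd)
}
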