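# Model bundle persistence: a directory with the configuration snapshot,
# the embedding table, the fold assignment, and one parameter file plus a
# JSON shape manifest per fold member.

#' Save a trained ensemble as a model bundle directory
#'
#' Layout: `config.yaml`, `embeddings.tsv`, `folds.tsv`,
#' `fold<i>/params.rds` and `fold<i>/manifest.json`.
#'
#' @param ensemble a [FoldEnsemble].
#' @param dir bundle directory (created if needed).
#' @return `dir`, invisibly.
#' @export
saveModelBundle <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(ensemble@config, file.path(dir, "config.yaml"))
  writeEmbeddings(ensemble@embeddings, file.path(dir, "embeddings.tsv"))
  write.table(ensemble@folds, file.path(dir, "folds.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (f in seq_along(ensemble@members)) {
    fd <- file.path(dir, sprintf("fold%d", f))
    dir.create(fd, showWarnings = FALSE)
    p <- ensemble@members[[f]]
    saveRDS(p, file.path(fd, "params.rds"))
    manifest <- list(
      heads = length(p@W),
      d = nrow(p@W[[1L]]),
      hidden = ncol(p@W[[1L]]),
      fc = c(nrow(p@fcW1), ncol(p@fcW1), 1L),
      slope = p@slope, edge_bias = p@edgeBias, dropout = p@dropout,
      best_epoch = if (length(ensemble@history) >= f)
        ensemble@history[[f]]$epoch[which.min(ensemble@history[[f]]$val_loss)]
      else NA
    )
    jsonlite::write_json(manifest, file.path(fd, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}

#' Load a model bundle saved by [saveModelBundle()]
#'
#' @param dir bundle directory.
#' @return a [FoldEnsemble].
#' @export
loadModelBundle <- function(dir) {
  cfgf <- file.path(dir, "config.yaml")
  if (!file.exists(cfgf)) stop(sprintf("not a model bundle: %s", dir))
  config <- yaml::read_yaml(cfgf)
  emb <- readEmbeddings(file.path(dir, "embeddings.tsv"),
                        meta = list(restored = TRUE))
  if (emb@k != config$k)
    stop(sprintf("bundle config k=%d does not match embeddings k=%d",
                 config$k, emb@k))
  folds <- read.delim(file.path(dir, "folds.tsv"),
                      stringsAsFactors = FALSE)
  members <- lapply(seq_len(config$folds), function(f)
    readRDS(file.path(dir, sprintf("fold%d", f), "params.rds")))
  new("FoldEnsemble", members = members, embeddings = emb,
      folds = folds, config = config, history = list())
}

#' Write a run manifest
#'
#' Records the command, configuration, seeds, input/output paths and
#' timing of a pipeline run, sufficient to re-execute it. Written
#' atomically (temp file + rename).
#'
#' @param path output JSON path.
#' @param command command name.
#' @param config configuration list.
#' @param inputs,outputs named path lists.
#' @param seed seed(s) used.
#' @param started POSIXct start time.
#' @return `path`, invisibly.
#' @export
writeRunManifest <- function(path, command, config = list(),
                             inputs = list(), outputs = list(),
                             seed = NA, started = Sys.time()) {
  manifest <- list(
    command = command,
    package_version = as.character(packageVersion("cncgat")),
    seed = seed,
    config = config,
    inputs = inputs,
    outputs = outputs,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  file.rename(tmp, path)
  invisible(path)
}
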