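# Persistence helpers: estimators as a directory of JSON files, fit
# results as JSON.

#' Save / load a trained estimator
#'
#' The estimator is stored as a directory: \code{weights.json} (all
#' parameter arrays with their dimensions), \code{state.json} (batch-norm
#' running statistics), \code{config.json} and \code{stats.json}
#' (normalization statistics).
#'
#' @param est a \code{dot_cnn}.
#' @param dir directory to create/overwrite.
#' @return \code{load_estimator} returns the \code{dot_cnn}.
#' @export
save_estimator <- function(est, dir) {
  stopifnot(inherits(est, "dot_cnn"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wj <- lapply(est$params, function(p)
    list(dim = if (is.null(dim(p))) length(p) else dim(p), data = as.vector(p)))
  jsonlite::write_json(wj, file.path(dir, "weights.json"),
                       digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(est$state, file.path(dir, "state.json"), digits = NA)
  cfg <- est$config; class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       digits = NA, auto_unbox = TRUE)
  st <- est$stats; class(st) <- NULL
  jsonlite::write_json(c(st, list(fine_tuned = est$fine_tuned,
                                  val_loss = est$val_loss)),
                       file.path(dir, "stats.json"),
                       digits = NA, auto_unbox = TRUE)
  utils::write.csv(est$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname save_estimator
#' @export
load_estimator <- function(dir) {
  wj <- jsonlite::read_json(file.path(dir, "weights.json"),
                            simplifyVector = TRUE)
  params <- lapply(wj, function(p) {
    if (length(p$dim) > 1L) array(p$data, p$dim) else as.numeric(p$data)
  })
  state <- jsonlite::read_json(file.path(dir, "state.json"),
                               simplifyVector = TRUE)
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  int_fields <- c("kernel", "lr_decay_every", "batch_size", "epochs",
                  "early_stop_every", "patience", "input_len", "n_out", "seed")
  cfg[int_fields] <- lapply(cfg[int_fields], as.integer)
  cfg$filters <- as.integer(cfg$filters)
  cfg$fc_width <- as.integer(cfg$fc_width)
  class(cfg) <- "cnn_config"
  stj <- jsonlite::read_json(file.path(dir, "stats.json"),
                             simplifyVector = TRUE)
  stats <- structure(stj[c("feature_mean", "feature_sd",
                           "label_mean", "label_sd")], class = "norm_stats")
  history <- utils::read.csv(file.path(dir, "history.csv"))
  structure(list(params = params, state = state, config = cfg, stats = stats,
                 history = history, val_loss = stj$val_loss,
                 fine_tuned = isTRUE(stj$fine_tuned)),
            class = "dot_cnn")
}

#' Serialize a fit result as JSON
#'
#' @param fit a \code{dot_fit}.
#' @param path file to write; if NULL the JSON string is returned.
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "dot_fit"))
  js <- jsonlite::toJSON(list(estimate = as.list(fit$estimate),
                              method = fit$method,
                              iterations = fit$iterations,
                              residual = fit$residual,
                              converged = fit$converged),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
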