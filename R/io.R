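#' Serialise a model to JSON
#'
#' Weights are written as nested arrays together with all hyperparameters
#' and the init seed, at maximum numeric precision, so a state can be
#' archived alongside simulation output and restored later.
#'
#' @param model A `diva` or `brdiva` object.
#' @return A JSON string.
#' @export
model_to_json <- function(model) {
  stopifnot(inherits(model, "diva") || inherits(model, "brdiva"))
  payload <- unclass(model)
  payload$.class <- class(model)[1L]
  jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE, null = "null")
}

#' Restore a model from JSON
#'
#' @param txt A JSON string produced by [model_to_json()].
#' @return The restored `diva` or `brdiva` object.
#' @export
model_from_json <- function(txt) {
  p <- jsonlite::fromJSON(txt)
  cls <- p$.class
  p$.class <- NULL
  as_mat <- function(m) matrix(as.numeric(m), nrow(m), ncol(m))
  for (nm in intersect(c("W_enc", "W_mu", "W_logvar"), names(p))) {
    p[[nm]] <- as_mat(p[[nm]])
  }
  if (!is.null(p$W_dec)) {
    # a list of equal-shape matrices may come back as a 3-d array
    p$W_dec <- if (is.list(p$W_dec)) {
      lapply(p$W_dec, as_mat)
    } else {
      lapply(seq_len(dim(p$W_dec)[1L]), function(i) as_mat(p$W_dec[i, , ]))
    }
  }
  for (nm in c("n_inputs", "n_hidden", "n_categories")) {
    p[[nm]] <- as.integer(p[[nm]])
  }
  structure(p, class = cls)
}

#' Write / read a trial table as CSV
#'
#' Plain tidy CSV, one row per trial; reading restores the `shj_trials`
#' class so downstream analyses behave identically on a round-tripped table.
#'
#' @param trials An `shj_trials` data.frame.
#' @param path File path.
#' @return `write_trials_csv` returns `path` invisibly; `read_trials_csv`
#'   returns the trial table.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  int_cols <- intersect(c("type", "participant", "block", "trial",
                          "stimulus", "response", "correct"), names(df))
  for (cn in int_cols) df[[cn]] <- as.integer(df[[cn]])
  if ("beta" %in% names(df)) df$beta <- as.numeric(df$beta)
  class(df) <- c("shj_trials", "data.frame")
  df
}

#' Save / load a simulation configuration
#'
#' JSON round trip: `load_config(save_config(cfg, path))` reproduces `cfg`.
#'
#' @param config A [sim_config()] object.
#' @param path File path.
#' @return `save_config` returns `path` invisibly; `load_config` the config.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  jsonlite::write_json(unclass(config), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  p <- jsonlite::fromJSON(path)
  sim_config(model = p$model, types = p$types,
             n_participants = p$n_participants, n_blocks = p$n_blocks,
             betas = if (length(p$betas)) p$betas else beta_grid(),
             base_seed = p$base_seed, learning_rate = p$learning_rate,
             sensitivity = p$sensitivity,
             attention_breadth = p$attention_breadth,
             weight_range = p$weight_range, n_hidden = p$n_hidden)
}

#' Write a run manifest
#'
#' A JSON sidecar recording the config snapshot, base seed, package version
#' and the MD5 hash of every output file, sufficient to reproduce any output
#' exactly.
#'
#' @param config The [sim_config()] used.
#' @param files Character vector of output file paths.
#' @param path Manifest destination.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, files, path) {
  manifest <- list(
    package = "brdiva",
    version = as.character(utils::packageVersion("brdiva")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    base_seed = config$base_seed,
    config = unclass(config),
    outputs = lapply(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
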