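# Run configuration: defaults, strict YAML loading, config hashing, and
# JSON-lines run logging.

#' Default run configuration
#'
#' Full-scale defaults: 1000 diffusion steps, latent/token dimension 256,
#' Adam with initial learning rate 1e-4 and weight decay 0.01, cosine
#' annealing, batch size 32, 100 epochs, horizons 180/365/730 days. The toy
#' profile shrinks the expensive knobs (50 diffusion steps, latent 32, 10
#' epochs) to desk scale while leaving the method untouched.
#'
#' @param profile `"toy"` (default) or `"paper_scale"`.
#' @return named list of class `pd_config`.
#' @export
default_config <- function(profile = c("toy", "paper_scale")) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    latent_dim = 256L,
    diffusion_steps = 1000L,
    learning_rate = 1e-4,
    weight_decay = 0.01,
    lr_schedule = "cosine_annealing",
    batch_size = 32L,
    epochs = 100L,
    horizons = c(180L, 365L, 730L),
    n_mamba_blocks = 2L,
    d_state = 8L,
    d_k = 32L,
    lambda_prompt = 1,
    lambda_fusion = 1,
    patch_size = c(8L, 8L, 8L),
    schedule_kind = "linear",
    gate_mode = "self",
    volume_shape = c(16L, 16L, 16L),
    n_candidates = 1L,
    seed = 1L,
    ablation = character(0))
  if (profile == "toy") {
    cfg$latent_dim <- 32L
    cfg$diffusion_steps <- 50L
    cfg$epochs <- 10L
    cfg$learning_rate <- 1e-3
  }
  structure(cfg, class = "pd_config")
}

#' Load a configuration file (strict YAML)
#'
#' Flat key/value YAML; unknown keys are rejected rather than ignored, so
#' ablation-study typos fail loudly.
#'
#' @param path YAML file path.
#' @param base config to override (default [default_config()]).
#' @return a `pd_config`.
#' @export
read_config <- function(path, base = default_config()) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(base))
  assert_that(length(unknown) == 0,
              paste("unknown config keys:", paste(unknown, collapse = ", ")))
  for (nm in names(vals)) base[[nm]] <- vals[[nm]]
  base
}

#' Short stable hash of a configuration (FNV-1a over its JSON form)
#' @param cfg any jsonlite-serializable object.
#' @return 8-hex-digit character hash.
#' @export
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  # 32-bit FNV-1a in double arithmetic; the multiply is split 16/16 bits so
  # intermediates stay below 2^53
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- h - (h %% 256) + bitwXor(h %% 256, b %% 256)
    h <- ((((h %/% 65536) * p) %% 65536) * 65536 + (h %% 65536) * p) %%
      4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' Append a structured JSON-lines entry to a run log
#' @param log_file path (created if needed); `NULL` disables logging.
#' @param stage stage name.
#' @param ... further scalar fields.
#' @return invisibly, the entry.
#' @export
log_run <- function(log_file, stage, ...) {
  entry <- c(list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  stage = stage), list(...))
  if (!is.null(log_file)) {
    con <- file(log_file, open = "a")
    on.exit(close(con))
    writeLines(as.character(jsonlite::toJSON(entry, auto_unbox = TRUE,
                                             digits = NA)), con)
  }
  invisible(entry)
}
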