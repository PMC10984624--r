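#' Write a run to disk (JSONL trajectory + CSV summary + config snapshot)
#'
#' Serializes an [run_agent()] result into a directory: `trials.jsonl` (one
#' JSON record per trajectory row, full numeric precision), `trait_steps.csv`,
#' `config.json` (niche configuration, seed, trial count and config digest)
#' and `agent.json` (a lossless serialization of the final agent state,
#' including Dirichlet stores and the precision belief).
#'
#' @param run An `esteem_run`.
#' @param path Directory to write into (created if needed).
#' @return `path`, invisibly.
#' @seealso [read_run()]
#' @export
write_run <- function(run, path) {
  stopifnot(inherits(run, "esteem_run"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  lines <- vapply(seq_len(nrow(run$trials)), function(i) {
    row <- as.list(run$trials[i, ])
    row$self_image_belief <- row$self_image_belief[[1]]
    as.character(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA,
                                  null = "null", na = "null"))
  }, character(1))
  writeLines(lines, file.path(path, "trials.jsonl"))
  readr::write_csv(run$trait_steps, file.path(path, "trait_steps.csv"))
  cfg <- list(
    niche = unclass(run$niche),
    seed = run$seed,
    n_trials = run$n_trials,
    digest = config_digest(list(niche = unclass(run$niche), seed = run$seed,
                                n_trials = run$n_trials))
  )
  writeLines(
    as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, null = "null",
                                  pretty = TRUE)),
    file.path(path, "config.json")
  )
  writeLines(as.character(jsonlite::serializeJSON(run$agent, digits = NA)),
             file.path(path, "agent.json"))
  writeLines(as.character(jsonlite::serializeJSON(run$niche, digits = NA)),
             file.path(path, "niche.json"))
  invisible(path)
}

#' Read a run back from disk
#'
#' Inverse of [write_run()]; numeric fields round-trip at full precision.
#' Malformed trajectory lines raise an error naming the file, line and
#' (when identifiable) the missing field.
#'
#' @param path Directory written by [write_run()].
#' @return An `esteem_run`.
#' @export
read_run <- function(path) {
  trials_file <- file.path(path, "trials.jsonl")
  lines <- readLines(trials_file)
  required <- c("trial", "tau", "action", "trait_map", "ac", "valence",
                "gamma", "policy_entropy", "vfe", "efe_selected",
                "efe_spread", "p_approval")
  rows <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i]),
      error = function(e) {
        stop(sprintf("trials.jsonl line %d: malformed JSON (%s)",
                     i, conditionMessage(e)), call. = FALSE)
      }
    )
    missing <- setdiff(required, names(rec))
    if (length(missing)) {
      stop(sprintf("trials.jsonl line %d: missing field '%s'", i, missing[1]),
           call. = FALSE)
    }
    tibble::tibble(
      trial = as.integer(rec$trial),
      tau = as.integer(rec$tau),
      observation = if (is.null(rec$observation)) NA_integer_ else as.integer(rec$observation),
      action = as.integer(rec$action),
      self_image_belief = list(as.numeric(rec$self_image_belief)),
      trait_map = rec$trait_map,
      ac = rec$ac,
      valence = rec$valence,
      gamma = rec$gamma,
      policy_entropy = rec$policy_entropy,
      vfe = rec$vfe,
      efe_selected = rec$efe_selected,
      efe_spread = rec$efe_spread,
      p_approval = rec$p_approval
    )
  })
  trials <- if (length(rows)) dplyr::bind_rows(rows) else empty_trials()
  trait_steps <- readr::read_csv(
    file.path(path, "trait_steps.csv"),
    col_types = readr::cols(
      step = readr::col_integer(), trial = readr::col_integer(),
      trait_map = readr::col_character(), .default = readr::col_double()
    )
  )
  cfg <- jsonlite::fromJSON(file.path(path, "config.json"))
  niche <- jsonlite::unserializeJSON(
    paste(readLines(file.path(path, "niche.json")), collapse = "\n")
  )
  agent <- jsonlite::unserializeJSON(
    paste(readLines(file.path(path, "agent.json")), collapse = "\n")
  )
  structure(
    list(
      trials = trials,
      trait_steps = trait_steps,
      agent = agent,
      niche = niche,
      seed = cfg$seed,
      n_trials = cfg$n_trials
    ),
    class = "esteem_run"
  )
}
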