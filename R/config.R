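#' Read a generative-model configuration from JSON or YAML
#'
#' Loads one single-level model document with keys `A`, `B`, `C`, `D`, `E`,
#' `horizon`, `beta0`, `actions`, `labels`. Matrices are row-major (a list
#' of rows); `B` is a list with one matrix per action. The document is
#' validated on load via [validate_aif_model()] with informative errors.
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return An [aif_model()].
#' @seealso [write_model_config()]
#' @export
read_model_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  doc <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyMatrix = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("model config must be .json, .yaml or .yml", call. = FALSE)
  )
  need <- c("A", "B", "C", "D")
  missing <- setdiff(need, names(doc))
  if (length(missing)) {
    stop(sprintf("model config %s: missing key '%s'", basename(path), missing[1]),
         call. = FALSE)
  }
  as_mat <- function(x, key) {
    m <- tryCatch(do.call(rbind, lapply(x, as.numeric)),
                  error = function(e) NULL)
    if (is.matrix(x)) m <- x
    if (is.null(m) || !is.numeric(m)) {
      stop(sprintf("model config %s: key '%s' is not a numeric matrix",
                   basename(path), key), call. = FALSE)
    }
    m
  }
  A <- as_mat(doc$A, "A")
  Bl <- doc$B
  if (is.array(Bl) && length(dim(Bl)) == 3L) {
    # jsonlite parses a list of row-major matrices to n_u x n x n
    B <- aperm(Bl, c(2, 3, 1))
  } else {
    B <- simplify2array(lapply(seq_along(Bl), function(u) as_mat(Bl[[u]], "B")))
  }
  model <- tryCatch(
    aif_model(
      A = A, B = B, C = unlist(doc$C), D = unlist(doc$D),
      E = if (!is.null(doc$E)) unlist(doc$E) else NULL,
      policies = if (is.null(doc$policies)) NULL
                 else if (is.matrix(doc$policies)) doc$policies
                 else do.call(rbind, doc$policies),
      horizon = doc$horizon %||% 1L,
      beta0 = doc$beta0 %||% 1,
      labels = doc$labels
    ),
    error = function(e) {
      stop(sprintf("model config %s: %s", basename(path), conditionMessage(e)),
           call. = FALSE)
    }
  )
  model
}

#' Write a generative-model configuration to JSON or YAML
#'
#' @param model An [aif_model()].
#' @param path Destination path (`.json`, `.yaml` or `.yml`).
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  doc <- list(
    A = apply(model$A, 1, as.numeric, simplify = FALSE),
    B = lapply(seq_len(model$n_actions), function(u) {
      apply(model$B[, , u], 1, as.numeric, simplify = FALSE)
    }),
    C = as.numeric(model$C[, 1]),
    D = as.numeric(model$D),
    E = as.numeric(model$E),
    policies = apply(model$policies, 1, as.integer, simplify = FALSE),
    horizon = model$horizon,
    beta0 = model$beta0,
    actions = model$labels$actions %||% as.character(seq_len(model$n_actions)),
    labels = model$labels
  )
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    writeLines(
      as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                    pretty = TRUE, null = "null")),
      path
    )
  } else {
    yaml::write_yaml(doc, path, precision = 15)
  }
  invisible(path)
}

#' Read a hierarchical-agent (and optional niche) configuration
#'
#' One JSON or YAML document with sections `state_level`, `trait_level`,
#' `trait_link`, `learning`, `agent` (top-level options such as `noise`,
#' `fixed_trait`) and optionally `niche` (fields of [niche_config()] or a
#' `scenario` name with overrides). Every section is optional; defaults are
#' the package defaults.
#'
#' @param path File path (`.json`, `.yaml` or `.yml`).
#' @return List with `agent` (a [hierarchical_agent()]) and `niche` (a
#'   [niche_config()] or `NULL`).
#' @export
read_agent_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  doc <- switch(ext,
    json = jsonlite::fromJSON(path),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("agent config must be .json, .yaml or .yml", call. = FALSE)
  )
  sspec <- do.call(state_level_spec, as_args(doc$state_level))
  tspec <- do.call(trait_level_spec, as_args(doc$trait_level))
  link_args <- as_args(doc$trait_link)
  for (f in c("omega", "gamma0", "e_tilt")) {
    if (!is.null(link_args[[f]])) link_args[[f]] <- unlist(link_args[[f]])
  }
  link <- do.call(trait_link, link_args)
  learn_args <- as_args(doc$learning)
  if (!is.null(learn_args$learn)) learn_args$learn <- unlist(learn_args$learn)
  learning <- do.call(learning_config, learn_args)
  agent_args <- as_args(doc$agent)
  agent <- do.call(hierarchical_agent, c(
    list(state_spec = sspec, trait_spec = tspec, link = link,
         learning = learning),
    agent_args
  ))
  niche <- NULL
  if (!is.null(doc$niche)) {
    nc <- doc$niche
    if (!is.null(nc$scenario)) {
      ov <- as_args(nc$overrides)
      if (!is.null(ov$approval_given_action)) {
        ov$approval_given_action <- unlist(ov$approval_given_action)
      }
      niche <- make_scenario(nc$scenario, ov)
    } else {
      nc$approval_given_action <- unlist(nc$approval_given_action)
      niche <- do.call(niche_config, as_args(nc))
    }
  }
  list(agent = agent, niche = niche)
}

#' @noRd
as_args <- function(x) {
  if (is.null(x)) list() else lapply(x, identity)
}
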