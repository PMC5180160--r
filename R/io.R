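SCHEMA_VERSION <- 1L

#' Write a task specification file
#'
#' Serialises a task (and, for preset bundles, the recommended agent
#' configuration) to the structured-text task-spec format: JSON (primary
#' dialect) or YAML, chosen by file extension. The round trip through
#' [read_task_spec()] is lossless.
#'
#' @param x A [task_spec()] or [preset_bundle][build_preset()].
#' @param path Output path ending in `.json`, `.yaml` or `.yml`.
#' @return `path`, invisibly.
#' @export
write_task_spec <- function(x, path) {
  bundle <- if (inherits(x, "preset_bundle")) x else {
    new_preset_bundle(x, NULL, character(), x$name)
  }
  task <- bundle$task
  doc <- list(
    schema_version = SCHEMA_VERSION,
    name = task$name,
    states = lapply(seq_len(nrow(task$states)), function(i) {
      list(name = task$states$state[i], u = task$states$u[i],
           terminal = task$states$terminal[i])
    }),
    transitions = lapply(seq_len(nrow(task$transitions)), function(i) {
      list(state = task$transitions$state[i],
           behaviour = task$transitions$behaviour[i],
           "next" = task$transitions$next_state[i],
           prob = task$transitions$prob[i])
    }),
    entry = lapply(seq_len(nrow(task$entry)), function(i) {
      list(state = task$entry$state[i], prob = task$entry$prob[i])
    }),
    start = task$start,
    attempt_closure = task$attempt_closure %||% "return")
  if (!is.null(task$observe)) {
    doc$observe <- lapply(seq_len(nrow(task$observe)), function(i) {
      list(state = task$observe$state[i],
           observation = task$observe$observation[i])
    })
  }
  if (length(task$meta)) {
    doc$meta <- task$meta
    if (!is.null(doc$meta$correct)) doc$meta$correct <- as.list(doc$meta$correct)
  }
  if (!is.null(bundle$agent)) doc$agent <- agent_to_list(bundle$agent)
  if (length(bundle$provenance)) doc$provenance <- as.list(bundle$provenance)

  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(doc, path)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

agent_to_list <- function(agent) {
  df2l <- function(df) if (is.null(df)) NULL else {
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  }
  out <- list(alpha_v = agent$alpha_v, alpha_w = agent$alpha_w,
              beta = agent$beta, chaining = agent$chaining)
  if (!is.null(agent$alpha_v_map)) out$alpha_v_map <- df2l(agent$alpha_v_map)
  if (!is.null(agent$alpha_w_map)) out$alpha_w_map <- df2l(agent$alpha_w_map)
  if (!is.null(agent$beta_map)) out$beta_map <- df2l(agent$beta_map)
  if (!is.null(agent$modulation)) out$modulation <- df2l(agent$modulation)
  if (!is.null(agent$v_init)) out$v_init <- df2l(agent$v_init)
  if (is.data.frame(agent$w_init)) {
    out$w_init_map <- df2l(agent$w_init)
  } else if (agent$w_init != 0) out$w_init <- agent$w_init
  out
}

list_to_agent <- function(lst) {
  l2df <- function(x) if (is.null(x)) NULL else {
    dplyr::bind_rows(lapply(x, tibble::as_tibble))
  }
  agent_config(
    alpha_v = if (!is.null(lst$alpha_v_map)) l2df(lst$alpha_v_map) else
      (lst$alpha_v %||% 0.1),
    alpha_v_default = lst$alpha_v,
    alpha_w = if (!is.null(lst$alpha_w_map)) l2df(lst$alpha_w_map) else
      (lst$alpha_w %||% 0.1),
    alpha_w_default = lst$alpha_w,
    beta = lst$beta %||% 1,
    beta_map = l2df(lst$beta_map),
    modulation = l2df(lst$modulation),
    v_init = l2df(lst$v_init),
    w_init = if (!is.null(lst$w_init_map)) l2df(lst$w_init_map) else
      (lst$w_init %||% 0),
    chaining = lst$chaining %||% TRUE)
}

#' Read a task specification file
#'
#' Parses and validates a JSON or YAML task-spec file. Schema violations
#' are collected and reported together, each naming the offending field or
#' edge; unknown extra fields produce a warning, not an error (forward
#' compatibility).
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `preset_bundle` (with `agent = NULL` when the file carries no
#'   agent block).
#' @export
read_task_spec <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  doc <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }

  known <- c("schema_version", "name", "states", "transitions", "entry",
             "start", "attempt_closure", "observe", "meta", "agent",
             "provenance")
  extra <- setdiff(names(doc), known)
  if (length(extra)) {
    warn(sprintf("Ignoring unknown field(s): %s.",
                 paste(extra, collapse = ", ")))
  }

  errs <- character()
  need <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  need(!is.null(doc$states), "missing `states`")
  need(!is.null(doc$transitions), "missing `transitions`")
  need(!is.null(doc$entry), "missing `entry`")
  if (length(errs)) {
    abort(paste0("Schema violations in ", path, ":\n",
                 paste0("- ", errs, collapse = "\n")))
  }

  states <- dplyr::bind_rows(lapply(seq_along(doc$states), function(i) {
    s <- doc$states[[i]]
    need(!is.null(s$name), sprintf("states[%d]: missing `name`", i))
    need(is.numeric(s$u %||% NA), sprintf("states[%d]: missing/bad `u`", i))
    tibble::tibble(state = s$name %||% sprintf("?%d", i),
                   u = as.numeric(s$u %||% NA),
                   terminal = isTRUE(s$terminal))
  }))
  transitions <- dplyr::bind_rows(lapply(seq_along(doc$transitions),
                                         function(i) {
    tr <- doc$transitions[[i]]
    for (f in c("state", "behaviour", "next", "prob")) {
      need(!is.null(tr[[f]]),
           sprintf("transitions[%d]: missing `%s`", i, f))
    }
    pr <- as.numeric(tr$prob %||% NA)
    if (is.finite(pr) && (pr < 0 || pr > 1)) {
      need(FALSE, sprintf(
        "transitions[%d]: probability %g out of [0, 1] on edge (%s, %s)",
        i, pr, tr$state %||% "?", tr$behaviour %||% "?"))
    }
    tibble::tibble(state = tr$state %||% "?", behaviour = tr$behaviour %||% "?",
                   next_state = tr[["next"]] %||% "?", prob = pr)
  }))
  entry <- dplyr::bind_rows(lapply(doc$entry, function(e) {
    tibble::tibble(state = e$state %||% "?", prob = as.numeric(e$prob %||% NA))
  }))
  observe <- if (!is.null(doc$observe)) {
    dplyr::bind_rows(lapply(doc$observe, function(o) {
      tibble::tibble(state = o$state %||% "?",
                     observation = o$observation %||% "?")
    }))
  }
  if (length(errs)) {
    abort(paste0("Schema violations in ", path, ":\n",
                 paste0("- ", errs, collapse = "\n")))
  }

  task <- task_spec(states, transitions, entry,
                    start = doc$start %||% NULL, observe = observe,
                    attempt_closure = doc$attempt_closure %||% "return",
                    name = doc$name %||% "task")
  if (!is.null(doc$meta)) {
    meta <- doc$meta
    if (!is.null(meta$correct)) meta$correct <- unlist(meta$correct)
    if (!is.null(meta$functional)) meta$functional <- unlist(meta$functional)
    task$meta <- meta
  }
  stop_if_invalid(task)
  agent <- if (!is.null(doc$agent)) list_to_agent(doc$agent)
  new_preset_bundle(task, agent,
                    provenance = unlist(doc$provenance) %||% character(),
                    name = task$name)
}

#' Write simulation outputs and a run manifest
#'
#' Writes the tabular outputs of a simulation or learning-time study as
#' CSV (comma separated, mandatory header row, UTF-8, `.` decimal
#' separator) together with a JSON run manifest carrying the tool version,
#' timestamp, full parameter echo, seeds, input-file digests and the output
#' file list — sufficient to re-execute the run bit-identically. Results
#' never go to the logging stream.
#'
#' Trace files have the exact columns `attempt, step, state, observation,
#' behaviour, next_state, next_observation, u, d_v, terminal`; study files
#' `pattern, l, m, replicate, seed, attempts, capped`.
#'
#' @param x A `chaining_sim`, `learning_time_study`, `oracle_values`, or a
#'   plain data frame.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @param context Named list merged into the manifest (e.g. subcommand,
#'   input digests).
#' @param format Table format: `"csv"` (default) or `"json"`. The manifest
#'   is always JSON.
#' @return Tibble of written files (invisibly); the manifest is always
#'   written.
#' @export
write_outputs <- function(x, dir, prefix = "run", context = list(),
                          format = c("csv", "json")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  put <- function(df, name) {
    p <- file.path(dir, paste0(prefix, "_", name, ".", format))
    if (format == "csv") {
      write.csv(df, p, row.names = FALSE, fileEncoding = "UTF-8")
    } else {
      jsonlite::write_json(df, p, dataframe = "rows", digits = NA,
                           pretty = TRUE)
    }
    files <<- c(files, p)
  }
  seeds <- list()
  params <- list()

  if (inherits(x, "chaining_sim")) {
    tr <- x$transitions %||% tibble::tibble(
      attempt = integer(), step = integer(), state = character(),
      observation = character(), behaviour = character(),
      next_state = character(), next_observation = character(),
      u = numeric(), d_v = numeric(), terminal = logical())
    put(tr[, c("attempt", "step", "state", "observation", "behaviour",
               "next_state", "next_observation", "u", "d_v", "terminal")],
        "traces")
    put(x$attempts, "attempts")
    if (!is.null(x$snapshots)) put(x$snapshots, "snapshots")
    put(x$v, "v_final")
    put(x$w, "w_final")
    seeds <- list(simulation = x$seed)
    params <- x$params
    params$agent <- agent_to_list(params$agent)
  } else if (inherits(x, "learning_time_study")) {
    put(as.data.frame(x), "estimates")
    put(as.data.frame(summarise_learning_times(x)), "summary")
    seeds <- list(replicates = x$seed)
  } else if (inherits(x, "oracle_values")) {
    put(tibble::tibble(state = names(x$w_star), w_star = as.numeric(x$w_star)),
        "w_star")
    put(x$v_star, "v_star")
    params <- list(method = x$method, residual = x$residual)
  } else if (is.data.frame(x)) {
    put(x, "table")
  } else {
    abort("Don't know how to write this object.")
  }

  manifest <- c(list(
    tool = "chainsim",
    version = as.character(packageVersion("chainsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = params,
    seeds = seeds,
    outputs = as.list(basename(files))), context)
  mp <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(tibble::tibble(file = c(files, mp)))
}

file_digests <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(setNames(as.character(tools::md5sum(paths)), basename(paths)))
}
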