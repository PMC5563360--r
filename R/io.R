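#' Read a model configuration file
#'
#' Configuration files describe a state space, its allowed transitions
#' and named merge candidates in YAML (or JSON, which YAML parses):
#' fields `states`, `absorbing`, `transitions` (list of `from`/`to`
#' pairs) and `merges` (name -> list with `group`/`groups` and optional
#' `label`/`labels`).
#'
#' @param path Path to the configuration file.
#' @return A list with `space` (a [state_space()]), `transitions` (data
#'   frame `from`, `to`, or `NULL`) and `merges` (named list of
#'   [merge_spec()]).
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$states)) stop("config must list 'states'")
  sp <- state_space(unlist(cfg$states),
                    absorbing = unlist(cfg$absorbing) %||% character())
  trans <- NULL
  if (!is.null(cfg$transitions)) {
    trans <- do.call(rbind, lapply(cfg$transitions, function(tr) {
      data.frame(from = tr$from, to = tr$to, stringsAsFactors = FALSE)
    }))
    bad <- setdiff(c(trans$from, trans$to), sp$states)
    if (length(bad)) stop("transitions mention unknown states: ",
                          paste(bad, collapse = ", "))
  }
  merges <- list()
  for (nm in names(cfg$merges)) {
    m <- cfg$merges[[nm]]
    groups <- if (!is.null(m$groups)) lapply(m$groups, unlist)
              else list(unlist(m$group))
    labels <- unlist(m$labels) %||% unlist(m$label)
    merges[[nm]] <- merge_spec(groups, labels = labels, space = sp)
  }
  model <- NULL
  if (!is.null(cfg$probabilities)) {
    ns <- length(sp$states)
    P <- matrix(0, ns, ns, dimnames = list(sp$states, sp$states))
    for (pr in cfg$probabilities) P[pr$from, pr$to] <- pr$prob
    model <- transition_model(
      sp, P,
      cost = unlist(cfg$cost) %||% NULL,
      utility = unlist(cfg$utility) %||% NULL,
      cycle_length = cfg$cycle_length %||% 1)
  }
  list(space = sp, transitions = trans, merges = merges, model = model)
}

#' Write a model configuration file
#'
#' Inverse of [read_model_config()]; a round trip through
#' `write_model_config()` and [read_model_config()] is loss-less.
#'
#' @param config A list as returned by [read_model_config()].
#' @param path Output path (YAML).
#' @return `path`, invisibly.
#' @export
write_model_config <- function(config, path) {
  cfg <- list(states = as.list(config$space$states))
  if (length(config$space$absorbing)) {
    cfg$absorbing <- as.list(config$space$absorbing)
  }
  if (!is.null(config$transitions)) {
    cfg$transitions <- lapply(seq_len(nrow(config$transitions)),
                              function(i) {
      list(from = config$transitions$from[i], to = config$transitions$to[i])
    })
  }
  if (length(config$merges)) {
    cfg$merges <- lapply(config$merges, function(m) {
      list(groups = lapply(m$groups, as.list),
           labels = as.list(m$labels))
    })
  }
  if (!is.null(config$model)) {
    m <- config$model
    idx <- which(m$P > 0, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    cfg$probabilities <- lapply(seq_len(nrow(idx)), function(i) {
      list(from = m$space$states[idx[i, 1]],
           to = m$space$states[idx[i, 2]],
           prob = m$P[idx[i, 1], idx[i, 2]])
    })
    cfg$cost <- as.list(m$cost)
    cfg$utility <- as.list(m$utility)
    cfg$cycle_length <- m$cycle_length
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a comparison table or VOI summary to file
#'
#' CSV output rounds AIC-scale columns to one decimal place, matching
#' standard presentation; JSON output keeps full precision and a
#' metadata record (seed, package version, input hash) sufficient to
#' reproduce the run.
#'
#' @param x A `comparison_table` (from [compare_structures()] and
#'   friends) or a named list of VOI summaries.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @param metadata Optional named list merged into the JSON metadata
#'   (e.g. `list(seed = 1)`).
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("csv", "json"),
                         metadata = list()) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unsupported format"))
  if (format == "csv") {
    if (!is.data.frame(x)) stop("CSV output requires a tabular result")
    y <- as.data.frame(x)
    for (col in intersect(c("loglik", "aic", "delta_aic"), names(y))) {
      y[[col]] <- round(y[[col]], 1)
    }
    utils::write.csv(y, path, row.names = FALSE, quote = TRUE)
  } else {
    payload <- list(
      results = if (is.data.frame(x)) as.data.frame(x) else x,
      metadata = c(metadata, list(
        package = "statemerge",
        version = as.character(utils::packageVersion("statemerge")),
        generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(path)
}
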