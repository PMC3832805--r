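TRIAL_PHASES <- c("pavlovian", "instrumental", "blank", "test")

#' Build a trial collection
#'
#' A trial collection is a data frame with one row per time bin and one
#' column per observable/action node holding 0 (absent), 1 (present) or NA
#' (unobserved), plus a `phase` tag and a `multiplicity` count used to
#' compress identical bins. Latent nodes never appear: they are always
#' marginalized.
#'
#' @param spec an `sbn_spec`.
#' @param states data frame (or matrix) whose columns are a subset of the
#'   observable/action nodes; missing columns are filled with NA
#'   (unobserved).
#' @param phase phase tag, recycled; one of `"pavlovian"`, `"instrumental"`,
#'   `"blank"`, `"test"`.
#' @param multiplicity positive integer count per row, recycled.
#' @return An object of class `sbn_trials` (a data frame).
#' @export
trials_frame <- function(spec, states, phase = "test", multiplicity = 1L) {
  obs <- observable_nodes(spec)
  states <- as.data.frame(states)
  unknown <- setdiff(names(states), obs)
  if (length(unknown)) {
    stop("unknown node column(s): ", paste(unknown, collapse = ", "),
         " (latent nodes are never observed)")
  }
  n <- nrow(states)
  out <- as.data.frame(matrix(NA_integer_, nrow = n, ncol = length(obs),
                              dimnames = list(NULL, obs)))
  for (nm in names(states)) out[[nm]] <- as.integer(states[[nm]])
  bad <- !vapply(out, function(v) all(is.na(v) | v %in% c(0L, 1L)), logical(1))
  if (any(bad)) {
    stop("states must be 0, 1 or NA; offending column(s): ",
         paste(obs[bad], collapse = ", "))
  }
  phase <- rep_len(as.character(phase), n)
  if (!all(phase %in% TRIAL_PHASES)) {
    stop("phase must be one of: ", paste(TRIAL_PHASES, collapse = ", "))
  }
  multiplicity <- rep_len(as.integer(multiplicity), n)
  if (any(is.na(multiplicity) | multiplicity < 1L)) {
    stop("multiplicity must be a positive integer")
  }
  n_observed <- rowSums(!is.na(out))
  if (any(n_observed == 0L & phase != "blank")) {
    stop("every non-blank trial must observe at least one node")
  }
  out$phase <- phase
  out$multiplicity <- multiplicity
  class(out) <- c("sbn_trials", "data.frame")
  out
}

#' Single-trial convenience constructor
#'
#' @param spec an `sbn_spec`.
#' @param ... node = value pairs (0, 1 or NA); unnamed nodes are unobserved.
#' @param phase,multiplicity as in [trials_frame()].
#' @return a one-row `sbn_trials`.
#' @export
trial_record <- function(spec, ..., phase = "test", multiplicity = 1L) {
  states <- list(...)
  trials_frame(spec, as.data.frame(states), phase = phase,
               multiplicity = multiplicity)
}

#' Combine trial collections
#' @param ... `sbn_trials` objects over the same network.
#' @return an `sbn_trials`.
#' @export
bind_trials <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("sbn_trials", "data.frame")
  rownames(out) <- NULL
  out
}

#' Aggregate identical trials
#'
#' Rows with identical observed states and phase are merged, summing their
#' multiplicities. The likelihood is invariant to this compression, which
#' speeds up MCMC by orders of magnitude on repetitive conditioning data.
#'
#' @param trials an `sbn_trials`.
#' @return an `sbn_trials` with unique (states, phase) rows.
#' @export
compress_trials <- function(trials) {
  cols <- setdiff(names(trials), "multiplicity")
  key <- do.call(paste, c(lapply(trials[cols], function(v) ifelse(is.na(v), ".", v)),
                          sep = "\r"))
  first <- !duplicated(key)
  out <- trials[first, , drop = FALSE]
  out$multiplicity <- as.integer(
    tapply(trials$multiplicity, key, sum)[key[first]])
  rownames(out) <- NULL
  class(out) <- c("sbn_trials", "data.frame")
  out
}

# Integer matrix view for the C++ kernels: one column per observable node
# in canonical order, NA encoded as -1.
as_trial_matrix <- function(trials, spec) {
  obs <- observable_nodes(spec)
  m <- as.matrix(as.data.frame(trials)[, obs, drop = FALSE])
  storage.mode(m) <- "integer"
  m[is.na(m)] <- -1L
  m
}

#' Write / read trials as CSV
#'
#' One row per bin; observable/action columns with values 0/1/NA plus
#' `phase` and `multiplicity` columns.
#'
#' @param trials an `sbn_trials`.
#' @param path file path.
#' @param spec the `sbn_spec` used to validate on reading.
#' @return `write_trials_csv` returns `path` invisibly; `read_trials_csv`
#'   returns an `sbn_trials`.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE, na = "NA",
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path, spec) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  trials_frame(spec, df[, setdiff(names(df), c("phase", "multiplicity")),
                        drop = FALSE],
               phase = df$phase, multiplicity = df$multiplicity)
}
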