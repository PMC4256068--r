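#' Write choice records to tidy CSV (+ JSON metadata sidecar)
#'
#' One row per trial with columns `subject`, `framing`, `opponent`, `trial`,
#' `a_self`, `a_opp`, `outcome`. Record metadata (models, parameters, seeds)
#' goes to a JSON sidecar so the CSV stays a plain, auditable table.
#'
#' @param records list of [choice_record()]s.
#' @param path CSV output path; the sidecar is `path` with a `.json`
#'   extension unless `sidecar` is given.
#' @param sidecar optional sidecar path; `NA` suppresses the sidecar.
#' @return Invisibly, `path`.
#' @export
write_choice_records <- function(records, path, sidecar = NULL) {
  if (inherits(records, "choice_record")) records <- list(records)
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    data.frame(subject = r$meta$subject %||% i,
               framing = r$meta$framing %||% "simulated",
               opponent = r$meta$opponent %||% r$meta$model_opp %||% "unknown",
               trial = seq_len(r$trials),
               a_self = r$a_self, a_opp = r$a_opp, outcome = r$outcome)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  if (is.null(sidecar)) sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (!is.na(sidecar))
    jsonlite::write_json(lapply(records, function(r)
      utils::modifyList(r$meta, list(trials = r$trials))),
      sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and validate choice records from tidy CSV
#'
#' Inverse of [write_choice_records()]. Sessions are the unique
#' (subject, framing, opponent) combinations; within each session trials
#' must be contiguous from 1, actions binary, and outcomes consistent with
#' the actions under the game's payoff table. Validation errors name the
#' offending row. An optional `missed` column (0/1) marks trials on which
#' the focal player failed to respond in time: a missed trial scores a
#' point for the other player (its outcome must be 0), is dropped from the
#' returned action sequences, and is counted in the record's
#' `meta$n_missed`. Simulated data never contain misses.
#'
#' @param path CSV path with the columns written by [write_choice_records()].
#' @param payoff a [payoff_table()] for outcome validation.
#' @return List of [choice_record()]s.
#' @export
read_choice_records <- function(path, payoff = hide_and_seek()) {
  df <- utils::read.csv(path)
  need <- c("subject", "framing", "opponent", "trial", "a_self", "a_opp",
            "outcome")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!"missed" %in% names(df)) df$missed <- 0L
  df$missed[is.na(df$missed)] <- 0L

  live <- df$missed == 0
  bad <- which(rowSums(is.na(df[need])) > 0 & live)
  if (length(bad)) stop("missing values in row ", bad[1])
  bad <- which(live & (!(df$a_self %in% 0:1) | !(df$a_opp %in% 0:1)))
  if (length(bad)) stop("non-binary action in row ", bad[1])
  bad <- which(!live & df$outcome != 0)
  if (length(bad))
    stop("missed trial must score for the other player (outcome 0), row ",
         bad[1])
  implied <- ifelse(live, trial_outcome(payoff,
                                        ifelse(live, df$a_self, 0),
                                        ifelse(live, df$a_opp, 0)), 0)
  bad <- which(live & df$outcome != implied)
  if (length(bad))
    stop("outcome inconsistent with actions in row ", bad[1])

  key <- interaction(df$subject, df$framing, df$opponent, drop = TRUE)
  lapply(split(df, key), function(g) {
    g <- g[order(g$trial), ]
    if (!identical(as.integer(g$trial), seq_len(nrow(g))))
      stop("non-contiguous trial index for subject ", g$subject[1],
           ", opponent ", g$opponent[1])
    keep <- g$missed == 0
    choice_record(g$a_self[keep], g$a_opp[keep], g$outcome[keep],
                  meta = list(subject = g$subject[1],
                              framing = g$framing[1],
                              opponent = g$opponent[1],
                              n_missed = sum(!keep)),
                  payoff = payoff)
  })
}

#' Write a fitted kernel table
#'
#' @param kernels list of `volterra_kernel` objects (named or not).
#' @param path CSV output path (columns: kernel, lag, self_weight,
#'   opp_weight).
#' @return Invisibly, `path`.
#' @export
write_kernels <- function(kernels, path) {
  if (inherits(kernels, "volterra_kernel")) kernels <- list(kernels)
  nm <- names(kernels) %||% seq_along(kernels)
  rows <- lapply(seq_along(kernels), function(i) {
    k <- kernels[[i]]
    data.frame(kernel = nm[i], lag = seq_len(k$L),
               self_weight = k$self_weights, opp_weight = k$opp_weights,
               intercept = k$intercept, fit_accuracy = k$fit_accuracy)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
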