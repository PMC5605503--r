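# Signal-detection and accuracy summaries per (group, condition, subtlety)
# cell: hit/false-alarm rates, d' with small-sample corrections, mean
# accuracy with SEM across participants.

# per-participant-per-cell rates and accuracy
.cell_rates <- function(responses) {
  key <- interaction(responses$participant_id, responses$condition,
                     responses$subtlety, drop = TRUE)
  split_rows <- split(seq_len(nrow(responses)), key)
  do.call(rbind, lapply(split_rows, function(ix) {
    r <- responses[ix, ]
    pres <- r$chase_present
    if (!any(!pres)) stop("undefined false-alarm rate: cell with no chase-absent trials")
    data.frame(
      participant_id = r$participant_id[1],
      group = r$group[1], condition = r$condition[1], subtlety = r$subtlety[1],
      n_present = sum(pres), n_absent = sum(!pres),
      hits = sum(r$response_present[pres]),
      fas = sum(r$response_present[!pres]),
      accuracy = mean(r$correct)
    )
  }))
}

# rate corrections that keep qnorm finite at 0/1 counts
.corrected_rate <- function(k, n, correction) {
  switch(correction,
    none = k / n,
    loglinear = (k + 0.5) / (n + 1),
    half_count = {
      r <- k / n
      r[k == 0] <- 1 / (2 * n[k == 0])
      r[k == n] <- 1 - 1 / (2 * n[k == n])
      r
    },
    stop("unknown correction: ", correction)
  )
}

#' d-prime table per group x condition x subtlety cell
#'
#' Computes each participant's hit rate (20 chase-present trials per cell in
#' the standard design) and false-alarm rate (5 chase-absent trials), applies
#' the chosen correction before the probit transform, takes
#' `d' = qnorm(H) - qnorm(FA)`, and averages over the participants of each
#' (group, condition, subtlety) cell. With so few chase-absent trials the
#' correction choice materially affects d'; `"loglinear"` uses
#' `(count + 0.5) / (n + 1)`, `"half_count"` replaces rates of 0 and 1 by
#' `1/(2n)` and `1 - 1/(2n)`, and `"none"` leaves extreme cells infinite.
#'
#' @param responses data frame as from [simulate_study()] (needs
#'   `response_present`).
#' @param correction `"loglinear"`, `"half_count"` or `"none"`.
#' @return data frame per cell: `group, condition, subtlety, hit_rate,
#'   fa_rate, dprime, sem_dprime, mean_accuracy, sem_accuracy, n`.
#' @export
dprime_table <- function(responses, correction = c("loglinear", "half_count", "none")) {
  correction <- match.arg(correction)
  cells <- .cell_rates(responses)
  cells$H <- .corrected_rate(cells$hits, cells$n_present, correction)
  cells$FA <- .corrected_rate(cells$fas, cells$n_absent, correction)
  cells$dprime <- stats::qnorm(cells$H) - stats::qnorm(cells$FA)
  .summarise_cells(cells)
}

#' Mean accuracy per group x condition x subtlety cell
#'
#' Mean of the per-participant accuracies with the standard error of the
#' mean (`SD / sqrt(n)`; 0 for a single participant).
#'
#' @param responses data frame as from [simulate_study()].
#' @return data frame per cell: `group, condition, subtlety, mean_accuracy,
#'   sem_accuracy, n`.
#' @export
accuracy_summary <- function(responses) {
  cells <- .cell_rates(responses)
  out <- .summarise_cells(cells)
  out[, c("group", "condition", "subtlety", "mean_accuracy", "sem_accuracy", "n")]
}

.summarise_cells <- function(cells) {
  key <- interaction(cells$group, cells$condition, cells$subtlety, drop = TRUE)
  sem <- function(v) if (length(v) < 2L) 0 else stats::sd(v) / sqrt(length(v))
  out <- do.call(rbind, lapply(split(cells, key), function(cc) {
    data.frame(
      group = cc$group[1], condition = cc$condition[1], subtlety = cc$subtlety[1],
      hit_rate = if (!is.null(cc$H)) mean(cc$H) else NA_real_,
      fa_rate = if (!is.null(cc$FA)) mean(cc$FA) else NA_real_,
      dprime = if (!is.null(cc$dprime)) mean(cc$dprime) else NA_real_,
      sem_dprime = if (!is.null(cc$dprime)) sem(cc$dprime) else NA_real_,
      mean_accuracy = mean(cc$accuracy),
      sem_accuracy = sem(cc$accuracy),
      n = nrow(cc)
    )
  }))
  out <- out[order(out$group, out$condition, out$subtlety), ]
  rownames(out) <- NULL
  out
}
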