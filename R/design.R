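# Within-participant trial list: 3 blocks (conditions) in counterbalanced
# order; per condition 6 practice trials then 75 test trials
# (3 subtleties x (20 chase-present + 5 chase-absent)), shuffled.

.conditions <- c("baseline", "social", "nonsocial")
.subtleties <- c(15, 45, 75)

# all 6 orderings of the three conditions, cycled across participants
.condition_orders <- function() {
  p <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  lapply(p, function(ix) .conditions[ix])
}

#' Build the full experimental design
#'
#' One row per trial for every participant: three condition blocks in a
#' counterbalanced order (the six permutations of baseline/social/nonsocial
#' cycled across participants), each block starting with 6 practice trials
#' (one chase-present and one chase-absent per subtlety) followed by 75 test
#' trials -- 20 chase-present and 5 chase-absent at each of the three
#' subtleties -- in a seeded random order. Every row carries a unique seed
#' from which its display can be regenerated.
#'
#' @param n_participants number of participants (>= 1).
#' @param subtleties chasing subtleties, degrees.
#' @param n_present,n_absent test trials per subtlety per condition.
#' @param seed master seed for trial ordering and per-trial seeds.
#' @return data frame with columns `participant_id, block_index, condition,
#'   subtlety, chase_present, is_practice, trial_index, seed`.
#' @examples
#' d <- build_design(6, seed = 1)
#' table(d$condition[!d$is_practice & d$participant_id == "P01"])
#' @export
build_design <- function(n_participants, subtleties = .subtleties,
                         n_present = 20, n_absent = 5, seed = 1L) {
  stopifnot(n_participants >= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  orders <- .condition_orders()
  per_block <- 2L * length(subtleties) + length(subtleties) * (n_present + n_absent)
  total <- n_participants * 3L * per_block
  trial_seeds <- sample.int(.Machine$integer.max - 1L, total)

  rows <- vector("list", n_participants * 3L)
  k <- 0L; seed_ptr <- 0L
  for (p in seq_len(n_participants)) {
    pid <- sprintf("P%02d", p)
    ord <- orders[[(p - 1L) %% 6L + 1L]]
    for (b in 1:3) {
      practice <- data.frame(
        subtlety = rep(subtleties, each = 2L),
        chase_present = rep(c(TRUE, FALSE), length(subtleties))
      )
      test <- data.frame(
        subtlety = rep(subtleties, each = n_present + n_absent),
        chase_present = rep(rep(c(TRUE, FALSE), c(n_present, n_absent)),
                            length(subtleties))
      )
      test <- test[sample.int(nrow(test)), ]
      blk <- rbind(cbind(practice, is_practice = TRUE),
                   cbind(test, is_practice = FALSE))
      n <- nrow(blk)
      k <- k + 1L
      rows[[k]] <- data.frame(
        participant_id = pid, block_index = b, condition = ord[b],
        subtlety = blk$subtlety, chase_present = blk$chase_present,
        is_practice = blk$is_practice, trial_index = seq_len(n),
        seed = trial_seeds[seed_ptr + seq_len(n)]
      )
      seed_ptr <- seed_ptr + n
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
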