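#' Block-design schedule parameters
#'
#' Parameters of a blocked working-memory experiment: three task loads
#' (1-, 2-, 3-back), each block preceded by an instruction (preparation)
#' screen and followed by a rest period.  Defaults reproduce the study
#' design: TR = 2 s, 8-s instruction screens, 10 blocks per load, task
#' blocks of at least 21 TRs (self-paced, so longer is possible) and
#' 10-12 s rest periods.
#'
#' @param tr_seconds duration of one TR in seconds (> 0).
#' @param n_blocks_per_condition number of blocks per task load (>= 0).
#' @param instruction_seconds duration of the instruction screen in
#'   seconds; must be a whole number of TRs.
#' @param block_trs_min minimum task-block length in TRs.  Actual lengths
#'   are drawn uniformly from `block_trs_min` to `block_trs_min + 6` to
#'   emulate self-paced variability.
#' @param rest_seconds_range inclusive range (low, high) of rest duration
#'   in seconds; must contain at least one whole multiple of `tr_seconds`.
#' @param seed RNG seed controlling block order and block/rest lengths.
#' @return An object of class `schedule_params`.
#' @export
schedule_params <- function(tr_seconds = 2,
                            n_blocks_per_condition = 10,
                            instruction_seconds = 8,
                            block_trs_min = 21,
                            rest_seconds_range = c(10, 12),
                            seed = 1L) {
  if (tr_seconds <= 0) stop("tr_seconds must be > 0")
  if (instruction_seconds <= 0) stop("instruction_seconds must be > 0")
  if (block_trs_min <= 0) stop("block_trs_min must be > 0")
  if (n_blocks_per_condition < 0) stop("n_blocks_per_condition must be >= 0")
  if (length(rest_seconds_range) != 2L ||
      rest_seconds_range[1L] > rest_seconds_range[2L])
    stop("rest_seconds_range must be (low, high) with low <= high")
  if (any(rest_seconds_range <= 0)) stop("rest_seconds_range must be > 0")
  prep_trs <- instruction_seconds / tr_seconds
  if (abs(prep_trs - round(prep_trs)) > 1e-9)
    stop("instruction_seconds (", instruction_seconds,
         ") is not a whole number of TRs at tr_seconds = ", tr_seconds)
  structure(list(tr_seconds = tr_seconds,
                 n_blocks_per_condition = as.integer(n_blocks_per_condition),
                 instruction_seconds = instruction_seconds,
                 block_trs_min = as.integer(block_trs_min),
                 rest_seconds_range = rest_seconds_range,
                 seed = seed),
            class = "schedule_params")
}

condition_labels <- function() {
  c("prep1", "task1", "prep2", "task2", "prep3", "task3", "rest")
}

#' Generate a block schedule
#'
#' Lays out the experiment as an ordered sequence of segments, one triplet
#' (preparation, task, rest) per block, with the block order over the three
#' loads randomized by the seed.  Conditions are labelled `prep1..prep3`,
#' `task1..task3` and `rest`.  TR indices are 0-based and segments are
#' half-open `[onset, onset + n_trs)`.
#'
#' @param params a [schedule_params()] object.
#' @return A data frame of class `block_schedule` with columns `condition`,
#'   `onset_tr`, `n_trs`, and attributes `tr_seconds` and `total_trs`.
#' @examples
#' sch <- make_schedule(schedule_params(seed = 1))
#' table(sch$condition)
#' @export
make_schedule <- function(params) {
  stopifnot(inherits(params, "schedule_params"))
  prep_trs <- as.integer(round(params$instruction_seconds / params$tr_seconds))
  rest_tr_lo <- ceiling(params$rest_seconds_range[1L] / params$tr_seconds - 1e-9)
  rest_tr_hi <- floor(params$rest_seconds_range[2L] / params$tr_seconds + 1e-9)
  if (rest_tr_hi < rest_tr_lo)
    stop("rest_seconds_range (", params$rest_seconds_range[1L], ", ",
         params$rest_seconds_range[2L],
         ") contains no whole number of TRs at tr_seconds = ",
         params$tr_seconds)
  nb <- params$n_blocks_per_condition
  out <- with_seed(params$seed, {
    loads <- sample(rep(1:3, each = nb))
    condition <- character(0); onset <- integer(0); len <- integer(0)
    cur <- 0L
    for (k in loads) {
      task_trs <- sample(params$block_trs_min:(params$block_trs_min + 6L), 1L)
      rest_trs <- if (rest_tr_hi > rest_tr_lo)
        sample(rest_tr_lo:rest_tr_hi, 1L) else rest_tr_lo
      condition <- c(condition, paste0("prep", k), paste0("task", k), "rest")
      onset <- c(onset, cur, cur + prep_trs, cur + prep_trs + task_trs)
      len <- c(len, prep_trs, task_trs, rest_trs)
      cur <- cur + prep_trs + task_trs + rest_trs
    }
    list(condition = condition, onset = onset, len = len, total = cur)
  })
  sch <- data.frame(condition = out$condition,
                    onset_tr = as.integer(out$onset),
                    n_trs = as.integer(out$len))
  structure(sch,
            class = c("block_schedule", "data.frame"),
            tr_seconds = params$tr_seconds,
            total_trs = as.integer(out$total))
}

#' Total length of a schedule in TRs
#' @param schedule a `block_schedule`.
#' @return integer TR count (0 for an empty schedule).
#' @export
schedule_total_trs <- function(schedule) {
  stopifnot(inherits(schedule, "block_schedule"))
  attr(schedule, "total_trs")
}

# run expr with a private RNG stream; NULL seed uses the current stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
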