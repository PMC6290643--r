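#' Assemble validated observed data from long-format learner logs
#'
#' Converts a long tibble of learner logs — one row per (learner, time,
#' item) with a binary response and a positive latency — plus a Q-matrix
#' table into the internal `mlm_data` structure used by the likelihood,
#' the sampler, and the diagnostics.
#'
#' Validation is strict: responses must be 0/1, latencies strictly
#' positive, Q entries binary with every item requiring at least one skill,
#' duplicated (learner, time, item) rows are rejected, every item must be
#' observed at exactly one time point, and every learner must have a
#' complete record (no missing cells — incomplete logs are not supported).
#'
#' @param data Tibble/data frame with columns `learner_id`, `time`,
#'   `item_id`, `response`, `rt_seconds`.
#' @param q_matrix Tibble/data frame with columns `item_id`,
#'   `skill_1 .. skill_K`, one row per item.
#' @return An object of class `mlm_data`: a list with `responses` and
#'   `latencies` (`N x J` matrices), `q` (`J x K`), `item_time` (length
#'   `J`), id lookup tables, and counts `n_learners`, `n_times`,
#'   `n_skills`, `n_items`.
#' @export
as_mlm_data <- function(data, q_matrix) {
  req <- c("learner_id", "time", "item_id", "response", "rt_seconds")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    stop("`data` is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"item_id" %in% names(q_matrix)) {
    stop("`q_matrix` must have an `item_id` column.", call. = FALSE)
  }
  skill_cols <- grep("^skill_", names(q_matrix), value = TRUE)
  if (length(skill_cols) == 0) {
    stop("`q_matrix` must have `skill_*` columns.", call. = FALSE)
  }
  data <- tibble::as_tibble(data)

  bad <- which(!data$response %in% c(0, 1))
  if (length(bad) > 0) {
    stop("Non-binary `response` in `data` rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(data$rt_seconds) | data$rt_seconds <= 0)
  if (length(bad) > 0) {
    stop("Non-positive `rt_seconds` in `data` rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(data[c("learner_id", "time", "item_id")])
  if (any(dup)) {
    stop("Duplicate (learner_id, time, item_id) in `data` rows: ",
         paste(utils::head(which(dup), 5), collapse = ", "), call. = FALSE)
  }

  q_raw <- as.matrix(q_matrix[skill_cols])
  if (any(is.na(q_raw)) || !all(q_raw %in% c(0, 1))) {
    stop("Q-matrix entries must be 0/1.", call. = FALSE)
  }
  if (any(rowSums(q_raw) == 0)) {
    stop("Every item must require at least one skill; offending item_id: ",
         paste(q_matrix$item_id[rowSums(q_raw) == 0], collapse = ", "),
         call. = FALSE)
  }

  # item -> time assignment must be a partition
  it <- unique(data[c("item_id", "time")])
  if (anyDuplicated(it$item_id) > 0) {
    stop("Each item must appear at a single time point.", call. = FALSE)
  }
  unknown <- setdiff(it$item_id, q_matrix$item_id)
  if (length(unknown) > 0) {
    stop("Items missing from the Q-matrix: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }

  learners <- sort(unique(data$learner_id))
  times <- sort(unique(data$time))
  if (!all(times == seq_along(times))) {
    stop("`time` must be the consecutive integers 1..T.", call. = FALSE)
  }
  it <- it[order(it$time, match(it$item_id, q_matrix$item_id)), ]
  items <- it$item_id
  N <- length(learners); J <- length(items); T_ <- length(times)

  if (nrow(data) != N * J) {
    stop("Incomplete data: expected ", N * J, " rows (", N, " learners x ",
         J, " items), found ", nrow(data),
         ". Missing records are not supported.", call. = FALSE)
  }

  ri <- match(data$learner_id, learners)
  ci <- match(data$item_id, items)
  X <- matrix(NA_integer_, N, J)
  L <- matrix(NA_real_, N, J)
  X[cbind(ri, ci)] <- as.integer(data$response)
  L[cbind(ri, ci)] <- data$rt_seconds
  if (anyNA(X)) {
    stop("Incomplete data: some (learner, item) cells are missing.",
         call. = FALSE)
  }

  q <- q_raw[match(items, q_matrix$item_id), , drop = FALSE]
  storage.mode(q) <- "integer"
  structure(list(
    responses = X, latencies = L, q = q,
    item_time = as.integer(it$time),
    learner_ids = learners, item_ids = items,
    n_learners = N, n_times = T_, n_skills = length(skill_cols),
    n_items = J
  ), class = "mlm_data")
}

#' @export
print.mlm_data <- function(x, ...) {
  cat("<mlm_data> ", x$n_learners, " learners, ", x$n_times, " time points, ",
      x$n_items, " items, ", x$n_skills, " skills\n", sep = "")
  invisible(x)
}

#' Read a learner-log dataset and Q-matrix from CSV files
#'
#' Reads the long-format data CSV (`learner_id,time,item_id,response,
#' rt_seconds`) and the Q-matrix CSV (`item_id,skill_1..skill_K`) written
#' by [write_learning_data()] (or produced externally in the same layout)
#' and validates them via [as_mlm_data()].
#'
#' @param data_path Path to the long-format data CSV.
#' @param q_path Path to the Q-matrix CSV.
#' @return A list with `data` (tibble), `q_matrix` (tibble), and `mlm`
#'   (the validated `mlm_data` object).
#' @export
read_learning_data <- function(data_path, q_path) {
  data <- tibble::as_tibble(utils::read.csv(data_path))
  q_matrix <- tibble::as_tibble(utils::read.csv(q_path))
  list(data = data, q_matrix = q_matrix, mlm = as_mlm_data(data, q_matrix))
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `data.csv` (long format), `qmatrix.csv`, and `truth.json` (true
#' latent states and parameters, including the simulation seed) into `dir`.
#'
#' @param sim A simulation result from [simulate_learning_data()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_learning_data <- function(sim, dir) {
  stopifnot(inherits(sim, "mlm_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(data = file.path(dir, "data.csv"),
             q = file.path(dir, "qmatrix.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(sim$data, paths["data"], row.names = FALSE)
  utils::write.csv(sim$q_matrix, paths["q"], row.names = FALSE)
  truth <- sim$truth
  truth$alpha <- apply(truth$alpha, c(1, 2), function(a) {
    paste(a, collapse = "")
  })
  jsonlite::write_json(
    list(seed = sim$seed, omega = sim$params$omega,
         lambda = c(sim$params$lambda0, sim$params$lambda1,
                    sim$params$lambda2),
         gstar = sim$params$gstar, mu1 = sim$params$mu1,
         sigma1_sq = sim$params$sigma1_sq, phi = sim$params$phi,
         sigma_tau_sq = sim$params$sigma_tau_sq, pi = sim$params$pi,
         items = sim$params$items, theta = truth$theta, tau = truth$tau,
         alpha = truth$alpha, D = truth$D),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
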