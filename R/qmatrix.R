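#' Generate a balanced synthetic Q-matrix
#'
#' Builds a binary item-by-skill requirement matrix suitable for
#' identification: every single-skill row (each skill measured in
#' isolation) appears at least once, and the remaining rows are drawn with
#' equal probability from the one- and two-skill patterns. The first `K`
#' rows form the single-skill completeness block, so `n_items = n_skills`
#' forces the identity matrix.
#'
#' @param n_items Number of items `J` (must be `>= n_skills`).
#' @param n_skills Number of skills `K`.
#' @param seed Optional seed; the same seed always yields the same matrix.
#' @return A `J x K` binary integer matrix with columns `skill_1..skill_K`.
#' @export
#' @examples
#' generate_q_matrix(4, 4, seed = 1) # forced to the 4 x 4 identity
#' generate_q_matrix(10, 4, seed = 1)
generate_q_matrix <- function(n_items, n_skills, seed = NULL) {
  stopifnot(n_skills >= 1)
  if (n_items < n_skills) {
    stop("`n_items` must be at least `n_skills` so every skill can be ",
         "measured in isolation.", call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  J <- as.integer(n_items); K <- as.integer(n_skills)

  single <- diag(1L, K)
  pool <- single
  if (K >= 2) {
    pairs <- utils::combn(K, 2)
    two <- t(apply(pairs, 2, function(idx) {
      r <- integer(K); r[idx] <- 1L; r
    }))
    pool <- rbind(single, two)
  }
  extra <- J - K
  q <- single
  if (extra > 0) {
    # balance: redraw until every skill is measured at least twice overall,
    # when the number of extra rows makes that feasible
    feasible <- 2 * extra >= K
    for (try in 1:1000) {
      rows <- sample(nrow(pool), extra, replace = TRUE)
      ex <- pool[rows, , drop = FALSE]
      if (!feasible || all(colSums(ex) >= 1)) break
    }
    q <- rbind(q, ex)
  }
  storage.mode(q) <- "integer"
  dimnames(q) <- list(NULL, paste0("skill_", seq_len(K)))
  q
}
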