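# Synthetic labeled sequence families with controlled divergence.
# Each family descends from an independent uniform-random ancestor;
# members accumulate i.i.d. per-site substitutions (uniform over the
# three alternative bases, a Jukes-Cantor-like neutral model) and,
# optionally, rare single indel events.  Entirely seed-determined, so
# every pipeline stage is testable without external data.

#' Simulate labeled sequence families
#'
#' @param n_families Number of families (independent random ancestors).
#' @param per_family Members per family.
#' @param length Ancestor length in bases.
#' @param substitution_rate Per-site substitution probability per
#'   member.
#' @param indel_rate Per-site probability of initiating an indel event
#'   (default 0: substitutions only).
#' @param indel_max_len Maximum indel length; event lengths are uniform
#'   on `[1, indel_max_len]`, insertions and deletions equally likely.
#' @param seed RNG seed; identical configurations produce identical
#'   output.
#' @return List with `seqs` (named character vector, ids like
#'   `fam01_seq03`), `labels` (named character vector, id -> family)
#'   and `ancestors`.
#' @export
#' @examples
#' fam <- simulate_families(n_families = 2, per_family = 3, length = 100,
#'                          substitution_rate = 0.01, seed = 1)
#' table(fam$labels)
simulate_families <- function(n_families = 4L, per_family = 10L,
                              length = 3000L, substitution_rate = 0.01,
                              indel_rate = 0, indel_max_len = 10L,
                              seed = 1L) {
  stopifnot(n_families >= 1, per_family >= 1, length >= 1,
            substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1, indel_max_len >= 1)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  seqs <- character(0)
  labels <- character(0)
  ancestors <- character(0)
  for (f in seq_len(n_families)) {
    fam <- sprintf("fam%02d", f)
    anc <- sample(bases, length, replace = TRUE)
    ancestors[fam] <- paste(anc, collapse = "")
    for (m in seq_len(per_family)) {
      member <- anc
      hit <- which(stats::runif(length) < substitution_rate)
      if (length(hit) > 0L) {
        # uniform over the three alternatives to the current base
        shift <- sample.int(3L, length(hit), replace = TRUE)
        member[hit] <- bases[(match(member[hit], bases) - 1L + shift) %% 4L
                             + 1L]
      }
      if (indel_rate > 0) {
        events <- which(stats::runif(length(member)) < indel_rate)
        for (at in rev(events)) {  # back-to-front keeps positions valid
          len <- sample.int(indel_max_len, 1L)
          if (stats::runif(1) < 0.5) {
            member <- member[-(at:min(at + len - 1L, length(member)))]
          } else {
            member <- append(member, sample(bases, len, replace = TRUE),
                             after = at)
          }
        }
      }
      id <- sprintf("%s_seq%02d", fam, m)
      seqs[id] <- paste(member, collapse = "")
      labels[id] <- fam
    }
  }
  list(seqs = seqs, labels = labels, ancestors = ancestors)
}
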