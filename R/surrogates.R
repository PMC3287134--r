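#' Surrogate specification
#'
#' @param surrogatetype one of `'trialshuffling'` (channel trial n is
#'   replaced by trial n+1, cyclically), `'trialreverse'` (sample order
#'   reversed), `'blockresampling'` (trial cut at a uniform random point
#'   c and the two blocks swapped), `'blockreverse1'` (reverse of the
#'   blockresampled trial), `'blockreverse2'` (first block reversed,
#'   second intact), `'blockreverse3'` (second block reversed, first
#'   intact).
#' @param target_channel label of the channel to manipulate; all other
#'   channels are left bit-identical.
#' @param seed integer seed for the random cut points.
#' @return An object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(surrogatetype, target_channel, seed = 1L) {
  allowed <- c("trialshuffling", "trialreverse", "blockresampling",
               "blockreverse1", "blockreverse2", "blockreverse3")
  if (!surrogatetype %in% allowed)
    stop("invalid surrogatetype '", surrogatetype, "'")
  structure(list(surrogatetype = surrogatetype,
                 target_channel = target_channel, seed = as.integer(seed)),
            class = "surrogate_spec")
}

#' Generate trial-based surrogate data
#'
#' Destroys the directed dependence between the target channel and its
#' partners by manipulating single-channel trials while preserving
#' within-trial structure; the per-trial sample multiset is conserved
#' for all block-based types.  Block cut points are drawn uniformly on
#' `1..N-1` (both blocks non-empty), independently per trial; the three
#' blockreverse variants consume the same cut draws as blockresampling
#' would under the same seed, so the family is comparable per trial.
#'
#' @param data a [raw_dataset()].
#' @param spec a [surrogate_spec()].
#' @return A new [raw_dataset()] with only the target channel modified.
#' @export
make_surrogate <- function(data, spec) {
  validate_raw_dataset(data)
  ch <- match(spec$target_channel, data$labels)
  if (is.na(ch)) stop("unknown channel '", spec$target_channel, "'")
  type <- spec$surrogatetype
  nt <- n_trials(data)
  if (type == "trialshuffling" && nt < 2L)
    stop("trialshuffling requires at least 2 trials")
  out <- data
  if (type == "trialshuffling") {
    src <- c(seq_len(nt)[-1L], 1L)  # trial n <- trial n+1, last <- first
    orig <- lapply(seq_len(nt), function(i) data$trials[[i]][ch, ])
    for (i in seq_len(nt)) {
      v <- orig[[src[i]]]
      m <- ncol(out$trials[[i]])
      if (length(v) != m)
        stop("trialshuffling requires equal trial lengths (trial ", i, ")")
      out$trials[[i]][ch, ] <- v
    }
    return(out)
  }
  if (type == "trialreverse") {
    for (i in seq_len(nt))
      out$trials[[i]][ch, ] <- rev(data$trials[[i]][ch, ])
    return(out)
  }
  # block types share the per-trial cut draws
  cuts <- with_seed(spec$seed, {
    vapply(seq_len(nt), function(i) {
      m <- ncol(data$trials[[i]])
      if (m < 2L) stop("trial ", i, " too short for block surrogates")
      sample.int(m - 1L, 1L)
    }, integer(1))
  })
  for (i in seq_len(nt)) {
    x <- data$trials[[i]][ch, ]
    cc <- cuts[i]
    first <- x[seq_len(cc)]
    second <- x[seq.int(cc + 1L, length(x))]
    out$trials[[i]][ch, ] <- switch(type,
      blockresampling = c(second, first),
      blockreverse1 = rev(c(second, first)),
      blockreverse2 = c(rev(first), second),
      blockreverse3 = c(first, rev(second)))
  }
  attr(out, "cuts") <- cuts
  out
}
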