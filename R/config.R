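#' Analysis configuration
#'
#' Builds the configuration object consumed by [prepare()] and the
#' statistics pipelines.  Field names and defaults follow the
#' configuration vocabulary of trial-based TE toolchains; any field not
#' supplied takes its default.
#'
#' @param sgncmb ordered source->target channel pairs: a two-column
#'   character matrix (or vector of length 2 for a single pair).
#' @param toi time window of interest, `c(from, to)` in seconds (NULL =
#'   whole trial).
#' @param predicttime_u estimated prediction time in **milliseconds**
#'   (converted to samples as `round(ms * fsample / 1000)`, clamped to
#'   >= 1).
#' @param optimizemethod `'ragwitz'` or `'cao'`.
#' @param ragdim dimensions scanned by the Ragwitz criterion.
#' @param ragtaurange min and max embedding delay in units of ACT.
#' @param ragtausteps number of equidistant steps in `ragtaurange`
#'   (minimum 5).
#' @param flagNei `'Range'` or `'Mass'` neighbour search for the local
#'   constant predictor.
#' @param sizeNei radius (Range) or neighbour mass (Mass).
#' @param repPred number of prediction points for the Ragwitz scan.
#' @param caodim dimensions scanned by the Cao criterion.
#' @param caokth_neighbors neighbour mass for the Cao criterion.
#' @param tau embedding delay in units of ACT (Cao; also the companion
#'   delay reported with a Cao-chosen dimension).
#' @param kth_neighbors neighbour mass for the TE estimator.
#' @param TheilerT Theiler exclusion window in samples, or `'ACT'` to use
#'   each channel's autocorrelation decay time.
#' @param trialselect `'no'`, `'range'` or `'ACT'`.
#' @param actthrvalue maximum ACT for trial selection (trialselect='ACT').
#' @param trial_from,trial_to trial range (trialselect='range').
#' @param minnrtrials minimum number of surviving trials.
#' @param maxlag lag range for the ACT computation (samples).
#' @param surrogatetype one of `'trialshuffling'`, `'trialreverse'`,
#'   `'blockresampling'`, `'blockreverse1'`, `'blockreverse2'`,
#'   `'blockreverse3'`.
#' @param shifttest `'yes'` or `'no'`.
#' @param shifttesttype `'TE > TEshift'` (conservative, alpha 0.05) or
#'   `'TEshift > TE'` (alpha 0.1).
#' @param shifttype `'predicttime'` or `'onesample'`.
#' @param permstatstype `'mean'`, `'indepsamplesT'` or `'depsamplesT'`.
#' @param numpermutation number of permutations.
#' @param tail 1 or 2.
#' @param alpha significance level.
#' @param correctm `'FDR'` or `'BONF'`.
#' @param fileidout stem for output file names.
#' @param dim,tau_samples optional override of the embedding dimension /
#'   delay (samples), bypassing the optimisation step.
#' @param design,uvar,ivar group design matrix and its unit/condition
#'   row indices (group pipeline only).
#' @param rng_seed master seed; every stochastic step derives its own
#'   stream from it.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(sgncmb = NULL,
                            toi = NULL,
                            predicttime_u = NULL,
                            optimizemethod = c("ragwitz", "cao"),
                            ragdim = 1:10,
                            ragtaurange = c(0.5, 1.5),
                            ragtausteps = 10L,
                            flagNei = c("Mass", "Range"),
                            sizeNei = 4L,
                            repPred = NULL,
                            caodim = 1:10,
                            caokth_neighbors = 4L,
                            tau = 1.5,
                            kth_neighbors = 4L,
                            TheilerT = "ACT",
                            trialselect = c("ACT", "no", "range"),
                            actthrvalue = NULL,
                            trial_from = NULL, trial_to = NULL,
                            minnrtrials = 12L,
                            maxlag = 1000L,
                            surrogatetype = "trialshuffling",
                            shifttest = "yes",
                            shifttesttype = "TE > TEshift",
                            shifttype = "predicttime",
                            permstatstype = "indepsamplesT",
                            numpermutation = 190100L,
                            tail = 2L,
                            alpha = 0.05,
                            correctm = "FDR",
                            fileidout = "teflow",
                            dim = NULL, tau_samples = NULL,
                            design = NULL, uvar = NULL, ivar = NULL,
                            rng_seed = 1L) {
  optimizemethod <- match.arg(optimizemethod)
  flagNei <- match.arg(flagNei)
  trialselect <- match.arg(trialselect)
  cfg <- list(sgncmb = normalize_sgncmb(sgncmb), toi = toi,
              predicttime_u = predicttime_u,
              optimizemethod = optimizemethod, ragdim = as.integer(ragdim),
              ragtaurange = ragtaurange, ragtausteps = as.integer(ragtausteps),
              flagNei = flagNei, sizeNei = sizeNei, repPred = repPred,
              caodim = as.integer(caodim),
              caokth_neighbors = as.integer(caokth_neighbors), tau = tau,
              kth_neighbors = as.integer(kth_neighbors), TheilerT = TheilerT,
              trialselect = trialselect, actthrvalue = actthrvalue,
              trial_from = trial_from, trial_to = trial_to,
              minnrtrials = as.integer(minnrtrials),
              maxlag = as.integer(maxlag), surrogatetype = surrogatetype,
              shifttest = shifttest, shifttesttype = shifttesttype,
              shifttype = shifttype, permstatstype = permstatstype,
              numpermutation = as.integer(numpermutation),
              tail = as.integer(tail), alpha = alpha, correctm = correctm,
              fileidout = fileidout, dim = dim, tau_samples = tau_samples,
              design = design, uvar = uvar, ivar = ivar,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "analysis_config"
  validate_analysis_config(cfg)
}

normalize_sgncmb <- function(sgncmb) {
  if (is.null(sgncmb)) return(NULL)
  if (is.character(sgncmb) && length(sgncmb) == 2L)
    sgncmb <- matrix(sgncmb, nrow = 1L)
  if (!is.matrix(sgncmb) || ncol(sgncmb) != 2L)
    stop("sgncmb must be an N x 2 matrix of source->target channel pairs")
  sgncmb
}

validate_analysis_config <- function(cfg) {
  chk <- function(val, allowed, name)
    if (!val %in% allowed)
      stop("invalid ", name, " '", val, "'; must be one of: ",
           paste(allowed, collapse = ", "))
  chk(cfg$surrogatetype, c("trialshuffling", "trialreverse", "blockresampling",
                           "blockreverse1", "blockreverse2", "blockreverse3"),
      "surrogatetype")
  chk(cfg$shifttest, c("yes", "no"), "shifttest")
  chk(cfg$shifttesttype, c("TE > TEshift", "TEshift > TE"), "shifttesttype")
  chk(cfg$shifttype, c("predicttime", "onesample"), "shifttype")
  chk(cfg$permstatstype, c("mean", "indepsamplesT", "depsamplesT"),
      "permstatstype")
  chk(cfg$correctm, c("FDR", "BONF"), "correctm")
  if (!cfg$tail %in% c(1L, 2L)) stop("tail must be 1 or 2")
  if (cfg$numpermutation < 1L) stop("numpermutation must be >= 1")
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) stop("alpha must be in (0, 1)")
  if (cfg$ragtausteps < 5L) stop("ragtausteps must be >= 5")
  if (!identical(cfg$TheilerT, "ACT") &&
      (!is.numeric(cfg$TheilerT) || cfg$TheilerT < 0))
    stop("TheilerT must be 'ACT' or a non-negative number of samples")
  cfg
}

#' Read an analysis configuration from a YAML or JSON file
#'
#' Field names in the file are the verbatim configuration vocabulary of
#' [analysis_config()].
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  fields <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(fields), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(fields$sgncmb))
    fields$sgncmb <- matrix(as.character(unlist(fields$sgncmb)),
                            ncol = 2L, byrow = TRUE)
  if (!is.null(fields$design))
    fields$design <- matrix(as.numeric(unlist(fields$design)),
                            nrow = length(fields$design), byrow = TRUE)
  do.call(analysis_config, fields)
}

# Prediction time in samples from the configured milliseconds.
u_samples <- function(cfg, fsample) {
  if (is.null(cfg$predicttime_u)) stop("predicttime_u is not set")
  max(1L, as.integer(round(cfg$predicttime_u * fsample / 1000)))
}

# Fingerprint of the preparation-relevant configuration, used by the
# group pipeline to refuse mixing datasets prepared under different
# settings.
config_fingerprint <- function(cfg) {
  keep <- c("sgncmb", "toi", "predicttime_u", "optimizemethod", "ragdim",
            "ragtaurange", "ragtausteps", "flagNei", "sizeNei", "repPred",
            "caodim", "caokth_neighbors", "tau", "kth_neighbors", "TheilerT",
            "trialselect", "actthrvalue", "trial_from", "trial_to",
            "minnrtrials", "maxlag", "dim", "tau_samples")
  s <- jsonlite::toJSON(cfg[keep], digits = NA, auto_unbox = TRUE,
                        null = "null")
  # 32-bit FNV-1a; stable across sessions, no extra dependency
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
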