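## Seeded generators for synthetic EEG, state-switching BOLD and clinical
## tables.  Defaults mirror the study conditions: 16 channels at 256 Hz
## with 6 s task/rest segments, 84 regions x 230 volumes at TR 2 s, and
## 13 + 11 subjects scored 0-66 at three time points.

## 1/f^a spectrally shaped Gaussian noise, unit variance.
.pinkNoise <- function(n, exponent = 1) {
    white <- stats::rnorm(n)
    spec <- stats::fft(white)
    f <- c(1, seq_len(n - 1))                 # guard DC
    f <- pmin(f, n - f + 1)                   # mirror for negative freqs
    shaped <- spec / f^(exponent / 2)
    shaped[1] <- 0
    x <- Re(stats::fft(shaped, inverse = TRUE)) / n
    x / stats::sd(x)
}

#' Simulate an epoched EEG recording with controllable mu ERD
#'
#' Generates paired task/rest segments on the 16-channel motor montage: a
#' ~10 Hz mu oscillation (random phase per trial and channel) on top of
#' 1/f background noise.  On the affected channels the task-segment mu
#' amplitude is scaled by \code{sqrt(erdRatio)}, so the task/rest mu
#' *power* ratio equals \code{erdRatio} and the expected suppression score
#' is \code{(1 - erdRatio) * 100}.  Unaffected channels show no ERD.
#'
#' @param nTrials trials per recording.
#' @param samplingRate Hz.
#' @param taskSeconds,restSeconds segment durations (equal by design).
#' @param muFreqHz mu oscillation frequency.
#' @param restMuAmp rest-state mu amplitude (arbitrary units).
#' @param erdRatio task/rest mu power ratio in (0, 1]; 1 = no ERD.
#' @param affectedChannels channels expressing the ERD; defaults to the
#'   ipsilesional hemisphere set for \code{lesionSide}.
#' @param noiseExponent spectral slope of the 1/f background.
#' @param snr ratio of mu amplitude to background-noise standard deviation.
#' @param lesionSide \code{"L"} or \code{"R"}.
#' @param seed integer seed; same seed, same recording.
#' @return an \code{\linkS4class{EpochedEEG}}.
#' @export
simulateEEG <- function(nTrials = 20, samplingRate = 256, taskSeconds = 6,
                        restSeconds = 6, muFreqHz = 10, restMuAmp = 10,
                        erdRatio = 0.8, affectedChannels = NULL,
                        noiseExponent = 1, snr = 5, lesionSide = "R",
                        seed = NULL) {
    if (erdRatio <= 0 || erdRatio > 1)
        stop("erdRatio must lie in (0, 1]")
    if (taskSeconds != restSeconds)
        stop("task and rest segments must have equal duration")
    if (snr <= 0 || restMuAmp <= 0) stop("snr and restMuAmp must be positive")
    labels <- montageChannels()
    if (is.null(affectedChannels))
        affectedChannels <- hemisphericChannels(labels,
                                                lesionSide)$ipsilesional
    if (!all(affectedChannels %in% labels))
        stop("affectedChannels outside the montage: ",
             paste(setdiff(affectedChannels, labels), collapse = ", "))
    if (!is.null(seed)) set.seed(seed)
    n <- round(taskSeconds * samplingRate)
    tgrid <- seq_len(n) / samplingRate
    noise_sd <- restMuAmp / snr
    task_amp <- restMuAmp * sqrt(erdRatio)
    trials <- lapply(seq_len(nTrials), function(i) {
        seg <- function(kind) {
            m <- matrix(0, length(labels), n,
                        dimnames = list(labels, NULL))
            for (ch in labels) {
                amp <- if (kind == "task" && ch %in% affectedChannels)
                    task_amp else restMuAmp
                phase <- stats::runif(1, 0, 2 * pi)
                m[ch, ] <- amp * sin(2 * pi * muFreqHz * tgrid + phase) +
                    noise_sd * .pinkNoise(n, noiseExponent)
            }
            m
        }
        list(rest = seg("rest"), task = seg("task"))
    })
    new("EpochedEEG", channelLabels = labels, samplingRate = samplingRate,
        trials = trials, lesionSide = lesionSide)
}

#' Simulate state-switching region-level BOLD time series
#'
#' A latent-state factor model for dynamic functional connectivity: the
#' brain alternates between \code{nStates} connectivity states with
#' geometric dwell times (mean \code{dwellMean} volumes).  Every region
#' loads on one of two latent factors; "stable" regions keep the same
#' factor in every state while "flexible" regions switch factors between
#' states, so their window-to-window connectivity profiles change and
#' their ground-truth temporal variability is higher.
#'
#' @param nRegions number of regions; defaults to the 84-region set of
#'   \code{\link{defaultSubnetworkMap}} (labels are taken from it when
#'   \code{nRegions} is 84).
#' @param T number of volumes.
#' @param trSeconds repetition time.
#' @param nStates number of latent connectivity states (>= 1; 1 gives a
#'   stationary series).
#' @param dwellMean mean state dwell time in volumes.
#' @param flexibleRegions labels/indices of the flexible set; default a
#'   third of the regions, spread over the label list.
#' @param loading factor loading of each region (connectivity strength).
#' @param noiseSd independent noise standard deviation.
#' @param subjectId,session,lesionSide metadata passed through.
#' @param seed integer seed.
#' @return \code{list(ts = RegionTimeSeries, flexible = character labels)}.
#' @export
simulateBOLD <- function(nRegions = 84, T = 230, trSeconds = 2,
                         nStates = 2, dwellMean = 30,
                         flexibleRegions = NULL, loading = 0.9,
                         noiseSd = 0.6, subjectId = "sim",
                         session = "unknown", lesionSide = "R",
                         seed = NULL) {
    if (nStates < 1L) stop("nStates must be at least 1")
    if (dwellMean < 1) stop("dwellMean must be at least 1 volume")
    labels <- if (nRegions == 84L) names(defaultSubnetworkMap())
              else sprintf("R%03d", seq_len(nRegions))
    if (!is.null(seed)) set.seed(seed)
    if (is.null(flexibleRegions))
        flexibleRegions <- labels[seq(1L, nRegions, by = 3L)]
    else if (is.numeric(flexibleRegions))
        flexibleRegions <- labels[flexibleRegions]
    if (!all(flexibleRegions %in% labels))
        stop("unknown flexible region labels")
    ## geometric-dwell latent state sequence
    states <- integer(T)
    s <- 1L
    p_switch <- 1 / dwellMean
    for (t in seq_len(T)) {
        states[t] <- s
        if (nStates > 1L && stats::runif(1) < p_switch)
            s <- sample(setdiff(seq_len(nStates), s), 1L)
    }
    ## two latent factors; stable regions keep factor 1 and their sign in
    ## every state, flexible regions get a state-specific factor and sign,
    ## so their inter-region correlation pattern differs across states
    flex <- labels %in% flexibleRegions
    sign_base <- sample(c(-1, 1), nRegions, replace = TRUE)
    fac_by_state <- matrix(1L, nStates, nRegions)
    sign_by_state <- matrix(rep(sign_base, each = nStates), nStates)
    if (nStates > 1L) for (st in 2:nStates) {
        fac_by_state[st, flex] <- 1L + (st - 1L) %% 2L
        sign_by_state[st, flex] <- sample(c(-1, 1), sum(flex),
                                          replace = TRUE)
    }
    factors <- matrix(stats::rnorm(2L * T), 2L, T)
    x <- matrix(0, nRegions, T, dimnames = list(labels, NULL))
    for (t in seq_len(T)) {
        st <- states[t]
        x[, t] <- loading * sign_by_state[st, ] *
            factors[cbind(fac_by_state[st, ], t)] +
            stats::rnorm(nRegions, sd = noiseSd)
    }
    ts <- regionTimeSeries(x, trSeconds = trSeconds, subjectId = subjectId,
                           session = session, lesionSide = lesionSide)
    list(ts = ts, flexible = labels[flex], states = states)
}

#' Simulate a clinical outcome table
#'
#' Baseline FMA-UE scores are drawn from a normal distribution, rounded
#' and clipped to the 0--66 scale; post and six-month scores add
#' group-specific change draws.  Missing six-month follow-ups are assigned
#' to the last subjects of each group.
#'
#' @param nPerGroup named integer vector, subjects per arm.
#' @param baselineMean,baselineSd baseline score distribution.
#' @param postChangeMean,fuChangeMean named per-group mean change at post
#'   and six-month follow-up.
#' @param changeSd standard deviation of the change draws.
#' @param missing6mo named per-group count of missing six-month scores.
#' @param seed integer seed.
#' @return a \code{\linkS4class{ClinicalTable}}.
#' @export
simulateClinical <- function(nPerGroup = c(guided = 13, sham = 11),
                             baselineMean = 24, baselineSd = 8,
                             postChangeMean = c(guided = 4, sham = 1),
                             fuChangeMean = c(guided = 4, sham = 1),
                             changeSd = 4,
                             missing6mo = c(guided = 0, sham = 0),
                             seed = NULL) {
    if (any(nPerGroup < 1)) stop("each group needs at least one subject")
    if (changeSd < 0 || baselineSd < 0) stop("negative standard deviation")
    if (!is.null(seed)) set.seed(seed)
    clip <- function(x) pmin(66, pmax(0, round(x)))
    rows <- list()
    sid <- 0L
    for (g in names(nPerGroup)) {
        n <- nPerGroup[[g]]
        pre <- clip(stats::rnorm(n, baselineMean, baselineSd))
        post <- clip(pre + stats::rnorm(n, postChangeMean[[g]], changeSd))
        fu <- clip(pre + stats::rnorm(n, fuChangeMean[[g]], changeSd))
        if (missing6mo[[g]] > 0)
            fu[(n - missing6mo[[g]] + 1L):n] <- NA
        rows[[g]] <- data.frame(
            subject_id = sprintf("S%d", sid + seq_len(n)),
            group = g,
            lesion_side = sample(c("L", "R"), n, replace = TRUE),
            fma_pre = pre, fma_post = post, fma_6mo = fu,
            stringsAsFactors = FALSE)
        sid <- sid + n
    }
    new("ClinicalTable", data = do.call(rbind, c(rows, make.row.names = FALSE)))
}
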