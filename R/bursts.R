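#' Max-interval burst parameters
#'
#' @param maxStartISI maximum initial ISI to open a burst (s).
#' @param maxEndISI maximum ISI to extend a burst (s).
#' @param minIBI minimum inter-burst interval (s); closer candidate bursts
#'   are merged.
#' @param minDuration minimum burst duration (s).
#' @param minSpikes minimum spikes per burst.
#' @return a validated [BurstParams-class].
#' @export
burstParams <- function(maxStartISI = 0.1, maxEndISI = 0.25, minIBI = 0.5,
                        minDuration = 0.05, minSpikes = 6) {
  new("BurstParams", maxStartISI = maxStartISI, maxEndISI = maxEndISI,
      minIBI = minIBI, minDuration = minDuration,
      minSpikes = as.integer(minSpikes))
}

#' @rdname burstParams
#' @export
defaultBurstParams <- function() burstParams()

#' Max-interval burst detection
#'
#' Single-pass scan: a candidate burst opens at spike *i* when the ISI to
#' the next spike is at most `maxStartISI`, extends while subsequent ISIs
#' stay at or below `maxEndISI`, and closes otherwise.  Adjacent candidates
#' whose last-spike-to-first-spike gap is below `minIBI` are then merged
#' (and re-measured), and finally candidates shorter than `minDuration` or
#' with fewer than `minSpikes` spikes are discarded.  The detect - merge -
#' filter order is pinned: it materially affects the output (a merged pair
#' of sub-threshold candidates can survive the spike-count filter).
#'
#' @param train strictly increasing spike times (s).
#' @param params a [BurstParams-class].
#' @return a [BurstSet-class]; burst duration is last spike minus first
#'   spike.
#' @examples
#' detectBursts(seq(0, 0.25, by = 0.05))            # one 6-spike burst
#' detectBursts(seq(0, 0.20, by = 0.05))            # 5 spikes: none
#' @export
detectBursts <- function(train, params = defaultBurstParams()) {
  n <- length(train)
  if (n > 1L && any(diff(train) <= 0)) stop("train must be strictly increasing")
  emptyTab <- data.frame(startIndex = integer(), endIndex = integer(),
                         tStart = numeric(), tEnd = numeric(),
                         nSpikes = integer(), duration = numeric())
  if (n < 2L) {
    return(new("BurstSet", table = emptyTab, params = params,
               nSpikesTrain = n))
  }
  isi <- diff(train)

  # scan for candidates
  starts <- integer(); ends <- integer()
  i <- 1L
  while (i <= n - 1L) {
    if (isi[i] <= params@maxStartISI) {
      j <- i + 1L
      while (j <= n - 1L && isi[j] <= params@maxEndISI) j <- j + 1L
      starts <- c(starts, i)
      ends <- c(ends, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(starts)) {
    return(new("BurstSet", table = emptyTab, params = params,
               nSpikesTrain = n))
  }

  # merge candidates separated by less than minIBI (left-to-right; merged
  # bursts are re-measured before the next gap is evaluated)
  ms <- starts[1L]; me <- ends[1L]
  mStarts <- integer(); mEnds <- integer()
  for (k in seq_along(starts)[-1L]) {
    if (train[starts[k]] - train[me] < params@minIBI) {
      me <- ends[k]
    } else {
      mStarts <- c(mStarts, ms); mEnds <- c(mEnds, me)
      ms <- starts[k]; me <- ends[k]
    }
  }
  mStarts <- c(mStarts, ms); mEnds <- c(mEnds, me)

  # filter on duration and spike count
  dur <- train[mEnds] - train[mStarts]
  cnt <- mEnds - mStarts + 1L
  ok <- dur >= params@minDuration & cnt >= params@minSpikes
  tab <- data.frame(startIndex = mStarts[ok], endIndex = mEnds[ok],
                    tStart = train[mStarts[ok]], tEnd = train[mEnds[ok]],
                    nSpikes = cnt[ok], duration = dur[ok])
  rownames(tab) <- NULL
  new("BurstSet", table = tab, params = params, nSpikesTrain = n)
}

#' Per-electrode burst feature summary
#'
#' @param train the spike train the bursts were detected on.
#' @param bursts a [BurstSet-class] from [detectBursts()].
#' @return list with `pctSpikesInBursts` (percent of all spikes falling
#'   inside bursts; 0 for a burstless train), `meanBurstDuration` (s, mean
#'   over bursts; `NA` if none) and `meanWithinBurstISI` (s, mean over all
#'   intra-burst ISIs pooled across bursts; `NA` if none).
#' @export
burstSummary <- function(train, bursts) {
  tab <- burstTable(bursts)
  if (nrow(tab) == 0L) {
    return(list(pctSpikesInBursts = 0,
                meanBurstDuration = NA_real_,
                meanWithinBurstISI = NA_real_))
  }
  inBurst <- sum(tab$nSpikes)
  isis <- unlist(lapply(seq_len(nrow(tab)), function(k) {
    diff(train[tab$startIndex[k]:tab$endIndex[k]])
  }))
  list(pctSpikesInBursts = 100 * inBurst / length(train),
       meanBurstDuration = mean(tab$duration),
       meanWithinBurstISI = mean(isis))
}
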