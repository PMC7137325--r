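#' Per-event normalized eCLIP density over a splice-site region
#'
#' Subtracts input read density from IP density (each in reads per
#' million), applies a pseudocount of one read (per-million normalized
#' against the input library, so the result is invariant to IP
#' sequencing depth) at each position, and scales the vector to sum to
#' one so every event weighs equally. By default the pseudocount is
#' applied to the subtracted density (`"post"`); `"pre"` adds one
#' per-million read to IP and input separately before subtraction.
#'
#' @param ip_density,input_density non-negative read-density vectors
#'   covering every region position.
#' @param ip_total,input_total mapped-read totals for RPM scaling.
#' @param pseudocount_where `"post"` (default) or `"pre"`.
#' @return numeric vector summing to 1 (negative positions permitted).
#' @export
event_normalized_density <- function(ip_density, input_density,
                                     ip_total, input_total,
                                     pseudocount_where = c("post", "pre")) {
  pseudocount_where <- match.arg(pseudocount_where)
  if (length(ip_density) != length(input_density))
    stop("density vectors must cover the same region")
  if (ip_total <= 0 || input_total <= 0) stop("totals must be positive")
  rpm_ip <- ip_density / ip_total * 1e6
  rpm_in <- input_density / input_total * 1e6
  if (pseudocount_where == "pre") {
    d <- (rpm_ip + 1e6 / ip_total) - (rpm_in + 1e6 / input_total)
  } else {
    d <- rpm_ip - rpm_in + 1e6 / input_total
  }
  s <- sum(d)
  if (s == 0) stop("degenerate event: subtracted density sums to zero")
  d / s
}

#' Trimmed-mean splicing map over events
#'
#' At each position the highest and lowest `trim` fraction of values
#' across events (floor(trim * n) from each tail) are removed and the
#' remaining values averaged.
#'
#' @param vectors matrix (events x positions) of normalized event
#'   vectors, or a list coercible to one.
#' @param trim tail fraction (default 0.025).
#' @return numeric vector of per-position trimmed means.
#' @export
build_splicing_map <- function(vectors, trim = 0.025) {
  m <- if (is.matrix(vectors)) vectors else do.call(rbind, vectors)
  n <- nrow(m)
  if (is.null(n) || n == 0L) stop("no event vectors")
  k <- floor(trim * n)
  if (k == 0L) return(colMeans(m))
  if (k == 1L) {
    rows <- lapply(seq_len(n), function(i) m[i, ])
    return((colSums(m) - Reduce(pmax, rows) - Reduce(pmin, rows)) / (n - 2L))
  }
  apply(m, 2L, function(v) {
    s <- sort(v)
    mean(s[seq.int(k + 1L, n - k)])
  })
}

#' Native-event confidence bands for a splicing map
#'
#' Draws `n_responsive` events from the native alternative 3' splice
#' site set `n_samples` times (with replacement by default), builds a
#' trimmed-mean map per draw, and returns the 0.5th and 99.5th
#' percentile per position.
#'
#' @param native_vectors matrix (native events x positions).
#' @param n_responsive events per draw (the responsive class size).
#' @param n_samples number of draws (default 1000).
#' @param trim tail fraction passed to [build_splicing_map].
#' @param replace sample with replacement (default TRUE).
#' @param seed RNG seed.
#' @return list: `ci_lo`, `ci_hi` (per-position percentile vectors).
#' @export
native_control_bands <- function(native_vectors, n_responsive,
                                 n_samples = 1000L, trim = 0.025,
                                 replace = TRUE, seed = 1L) {
  m <- if (is.matrix(native_vectors)) native_vectors else
    do.call(rbind, native_vectors)
  if (nrow(m) == 0L) stop("native set is empty")
  if (!replace && n_responsive > nrow(m))
    stop("cannot sample ", n_responsive, " events without replacement from ",
         nrow(m))
  maps <- with_seed(seed, {
    vapply(seq_len(n_samples), function(b) {
      idx <- sample.int(nrow(m), n_responsive, replace = replace)
      build_splicing_map(m[idx, , drop = FALSE], trim)
    }, numeric(ncol(m)))
  })
  list(ci_lo = apply(maps, 1L, stats::quantile, probs = 0.005, type = 1),
       ci_hi = apply(maps, 1L, stats::quantile, probs = 0.995, type = 1))
}

#' Native alternative 3' splice site events
#'
#' Events showing alternative usage in control cells: inclusion level
#' strictly between `lo` and `hi`.
#'
#' @param events event table with `inclusion_level`.
#' @param lo,hi strict bounds (defaults 0.05, 0.95).
#' @return filtered event table.
#' @export
native_events <- function(events, lo = 0.05, hi = 0.95) {
  events[events$inclusion_level > lo & events$inclusion_level < hi, ,
         drop = FALSE]
}

#' Full splicing map for an A3SS dataset
#'
#' Normalizes every event, builds the trimmed-mean map of the responsive
#' class and the native-event control bands sized to that class.
#'
#' @param dataset output of [simulate_a3ss_dataset] or an equivalently
#'   shaped list (`events`, `ip`, `input`, `ip_total`, `input_total`).
#' @param n_samples control-band draws (default 1000).
#' @param seed RNG seed for the band sampling.
#' @param pseudocount_where passed to [event_normalized_density].
#' @return list: `map`, `ci_lo`, `ci_hi`, `n_events`, `schema`,
#'   `vectors` (all normalized event vectors).
#' @export
splicing_map <- function(dataset, n_samples = 1000L, seed = 1L,
                         pseudocount_where = "post") {
  ev <- dataset$events
  vecs <- t(vapply(seq_len(nrow(ev)), function(i)
    event_normalized_density(dataset$ip[i, ], dataset$input[i, ],
                             dataset$ip_total, dataset$input_total,
                             pseudocount_where),
    numeric(ncol(dataset$ip))))
  rownames(vecs) <- ev$event_id
  resp <- ev$set_label == "responsive"
  nat <- native_events(ev)
  nat_idx <- match(nat$event_id, ev$event_id)
  nat_idx <- nat_idx[ev$set_label[nat_idx] == "native"]
  map <- build_splicing_map(vecs[resp, , drop = FALSE])
  bands <- native_control_bands(vecs[nat_idx, , drop = FALSE],
                                n_responsive = sum(resp),
                                n_samples = n_samples, seed = seed)
  list(map = map, ci_lo = bands$ci_lo, ci_hi = bands$ci_hi,
       n_events = sum(resp), schema = dataset$schema, vectors = vecs)
}
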