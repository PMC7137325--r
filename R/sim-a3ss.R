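#' Offsets of the alternative 3' splice site event region
#'
#' The event region concatenates one window per splice site, each 300 nt
#' of intron followed (5' to 3') by 50 nt of exon: distal 3' splice site
#' window first, then the proximal window, 700 positions total. Offsets
#' are -300..-1 (intron) and +1..+50 (exon) relative to each 3' splice
#' site.
#'
#' @param intron_nt,exon_nt window composition (defaults 300, 50).
#' @return data.frame `position` (1..2*(intron_nt+exon_nt)), `window`
#'   (`distal`/`proximal`), `offset`.
#' @export
a3ss_region_schema <- function(intron_nt = 300L, exon_nt = 50L) {
  w <- intron_nt + exon_nt
  offs <- c(seq.int(-intron_nt, -1L), seq.int(1L, exon_nt))
  data.frame(position = seq_len(2L * w),
             window = rep(c("distal", "proximal"), each = w),
             offset = rep(offs, 2L))
}

#' Simulate an alternative 3' splice site dataset
#'
#' Generates `n_events` knockdown-responsive events and `n_native`
#' native events (alternative usage in control cells, inclusion level
#' strictly between 0.05 and 0.95). Per-position IP and input read
#' densities are Poisson; responsive events carry a planted IP
#' enrichment bump (narrow Gaussian, default center at offset -80 from
#' the proximal 3' splice site).
#'
#' @param cfg a [sim_config] (`n_events`, `n_native`).
#' @param bump_offset planted bump center, offset from the proximal 3'
#'   splice site (default -80).
#' @param bump_height multiplicative peak height (default 10).
#' @param bump_sd Gaussian width in nt (default 3).
#' @param base_rate expected input reads per position (default 5).
#' @return list: `events` (event table with `set_label`), `ip`, `input`
#'   (event x position density matrices), `ip_total`, `input_total`,
#'   `schema`, `truth` (`event_id`, `responsive`, `bump_offset`).
#' @export
simulate_a3ss_dataset <- function(cfg, bump_offset = -80L, bump_height = 10,
                                  bump_sd = 3, base_rate = 5) {
  if (cfg$n_events + cfg$n_native < 1L) stop("need at least one event")
  schema <- a3ss_region_schema()
  R <- nrow(schema)
  if (bump_offset < min(schema$offset) || bump_offset > max(schema$offset))
    stop("bump offset outside the event window")
  with_seed(cfg$seed + 4L, {
    n <- cfg$n_events + cfg$n_native
    responsive <- c(rep(TRUE, cfg$n_events), rep(FALSE, cfg$n_native))
    events <- data.frame(
      event_id = sprintf("ev%04d", seq_len(n)),
      gene = sprintf("gene%04d", seq_len(n)),
      strand = "+",
      distal_3ss = 10000L, proximal_3ss = 10000L + 350L,
      inclusion_level = round(stats::runif(n, 0.06, 0.94), 3),
      set_label = ifelse(responsive, "responsive", "native"),
      stringsAsFactors = FALSE)
    bump_pos <- which(schema$window == "proximal" & schema$offset == bump_offset)
    shape <- exp(-((seq_len(R) - bump_pos)^2) / (2 * bump_sd^2))
    ip <- matrix(0, n, R); input <- matrix(0, n, R)
    for (i in seq_len(n)) {
      lam <- base_rate
      input[i, ] <- stats::rpois(R, lam)
      lam_ip <- lam * (1 + if (responsive[i]) bump_height * shape else 0)
      ip[i, ] <- stats::rpois(R, lam_ip)
    }
    rownames(ip) <- rownames(input) <- events$event_id
    list(events = events, ip = ip, input = input,
         ip_total = max(sum(ip), 1), input_total = max(sum(input), 1),
         schema = schema,
         truth = data.frame(event_id = events$event_id,
                            responsive = responsive,
                            bump_offset = ifelse(responsive, bump_offset, NA),
                            stringsAsFactors = FALSE))
  })
}

#' Simulate association-analysis fixtures
#'
#' Peak-set pairs with planted overlap fractions, a knockdown log2
#' fold-change table in which element-bound genes carry a planted
#' negative shift, an RBP-function annotation table and an interaction
#' pair list.
#'
#' @param cfg a [sim_config].
#' @param n_datasets number of peak sets (>= 2).
#' @param n_peaks peaks per set.
#' @param overlap planted overlap fraction between consecutive set pairs
#'   (set 1 vs 2, 3 vs 4, ...), in [0, 1].
#' @param n_genes genes in the knockdown table.
#' @param bound_fraction fraction of genes flagged element-bound.
#' @param shift planted negative log2FC shift of bound genes.
#' @return list: `peak_sets` (named list of interval data.frames),
#'   `log2fc` (`gene_id`, `log2fc`, `class`), `annotations`
#'   (`dataset_id`, `function_label`), `pairs` (two-column interaction
#'   list), `truth`.
#' @export
simulate_association_fixtures <- function(cfg, n_datasets = 4L,
                                          n_peaks = 200L, overlap = 0.5,
                                          n_genes = 600L,
                                          bound_fraction = 1 / 3,
                                          shift = 0.5) {
  stopifnot(n_datasets >= 2L)
  if (overlap < 0 || overlap > 1) stop("requested overlap must lie in [0, 1]")
  with_seed(cfg$seed + 5L, {
    peak_sets <- list()
    for (d in seq_len(n_datasets)) {
      if (d %% 2L == 1L) {
        starts <- sort(sample.int(1e6, n_peaks)) * 100L
        peak_sets[[d]] <- genomic_intervals(
          "chrSim", starts, starts + 50L, "+",
          name = sprintf("d%d_p%04d", d, seq_len(n_peaks)),
          fold_enrichment = 10, p_value = 1e-4)
      } else {
        prev <- peak_sets[[d - 1L]]
        n_shared <- round(overlap * n_peaks)
        shared <- prev[seq_len(n_shared), , drop = FALSE]
        shared$start <- shared$start + 10L  # offset but still overlapping
        shared$end <- shared$end + 10L
        n_extra <- n_peaks - n_shared
        ps <- shared
        if (n_extra > 0L) {
          extra_start <- sort(sample.int(1e6, n_extra)) * 100L + 7L
          extra <- genomic_intervals(rep("chrSim", n_extra), extra_start,
                                     extra_start + 43L, "+",
                                     name = "x", fold_enrichment = 10,
                                     p_value = 1e-4)
          ## keep extras disjoint from the partner set
          extra <- extra[!overlaps_any(extra, prev), , drop = FALSE]
          ps <- rbind(shared, extra)
        }
        ps$name <- sprintf("d%d_p%04d", d, seq_len(nrow(ps)))
        peak_sets[[d]] <- ps
      }
    }
    names(peak_sets) <- sprintf("DS%02d", seq_len(n_datasets))
    n_bound <- round(bound_fraction * n_genes)
    cls <- c(rep("bound", n_bound),
             rep("bgd_with_element", n_bound),
             rep("bgd", n_genes - 2L * n_bound))
    log2fc <- data.frame(
      gene_id = sprintf("g%05d", seq_len(n_genes)),
      log2fc = stats::rnorm(n_genes, 0, 0.3) -
        ifelse(cls == "bound", shift, 0),
      class = cls, stringsAsFactors = FALSE)
    annotations <- data.frame(
      dataset_id = names(peak_sets),
      function_label = rep(c("splicing", "rRNA_processing"),
                           length.out = n_datasets),
      stringsAsFactors = FALSE)
    pairs <- data.frame(a = names(peak_sets)[seq(1L, n_datasets - 1L, by = 2L)],
                        b = names(peak_sets)[seq(2L, n_datasets, by = 2L)],
                        stringsAsFactors = FALSE)
    list(peak_sets = peak_sets, log2fc = log2fc, annotations = annotations,
         pairs = pairs,
         truth = list(overlap = overlap, shift = shift))
  })
}
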