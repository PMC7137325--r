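#' Simulate an eCLIP library (two IP replicates + size-matched input)
#'
#' Input reads are drawn proportional to source abundance; IP reads apply
#' the planted per-family enrichment: a family with planted fold `m` gets
#' exactly `m` times its input share (remaining sources are rescaled to a
#' common factor so shares stay a distribution). Each pair carries a UMI
#' in its read id; PCR duplicates (identical coordinates + UMI, fresh
#' read serial) are injected at `duplicate_rate`; sequencing errors
#' substitute bases at `per_base_error_rate` with Phred qualities drawn
#' from a {40, 20} mixture. Every reported mapping of a pair appears in
#' the alignment table: all members of the true family (with exact
#' per-base mismatch bookkeeping), plus the unique genomic mapping for
#' reads drawn from gene exons or embedded element copies.
#'
#' @param cfg a [sim_config].
#' @param db a [family_db] from [build_family_database].
#' @param genome_ann optional output of [simulate_genome_annotation];
#'   when `NULL` all reads come from family transcripts.
#' @return list: `ip1`, `ip2`, `input` (alignment tables), `truth`
#'   (data.frame `sample`, `read_id`, `true_class`),
#'   `true_family_enrichment`.
#' @export
simulate_eclip_library <- function(cfg, db, genome_ann = NULL) {
  fams <- unique(db$members$family_id)
  unknown <- setdiff(names(cfg$enrichment), fams)
  if (length(unknown))
    stop("enrichment spec names unknown family: ",
         paste(unknown, collapse = ", "))
  frag <- 2L * cfg$read_length
  ctx <- build_sim_context(cfg, db, genome_ann, frag)
  with_seed(cfg$seed + 2L, {
    w_in <- ctx$sources$weight
    w_ip <- apply_enrichment(ctx$sources, cfg$enrichment)
    samples <- list(
      ip1 = gen_sample(cfg, ctx, w_ip, frag, "ip1"),
      ip2 = gen_sample(cfg, ctx, w_ip, frag, "ip2"),
      input = gen_sample(cfg, ctx, w_in, frag, "input"))
    truth <- do.call(rbind, lapply(names(samples), function(s)
      data.frame(sample = s, samples[[s]]$truth, stringsAsFactors = FALSE)))
    list(ip1 = samples$ip1$aln, ip2 = samples$ip2$aln,
         input = samples$input$aln, truth = truth,
         true_family_enrichment = cfg$enrichment)
  })
}

## ---- source bookkeeping -------------------------------------------------

## integer encoding of sequences (A=1 C=2 G=3 T=4)
seq_to_int <- function(seq) match(strsplit(seq, "", fixed = TRUE)[[1L]], BASES)

## Sources: family members, embedded element copies (in the family
## transcript coordinate frame) and gene exons. Precomputes, per family,
## the integer sequence matrix and the sorted difference-position lists
## between every source and every mapping target (the family members).
build_sim_context <- function(cfg, db, genome_ann, frag) {
  members <- db$members
  src <- list(); fam_ctx <- list()
  has_gen <- !is.null(genome_ann)
  fam_share <- if (has_gen) 1 - cfg$genomic_share else 1
  fams <- unique(members$family_id)
  for (f in fams) {
    mem <- members[members$family_id == f, , drop = FALSE]
    mem <- mem[order(mem$priority), , drop = FALSE]
    seqs <- lapply(mem$transcript_id, function(id)
      seq_to_int(as.character(db$sequences[[id]])))
    tlen <- length(seqs[[1L]])
    smat <- do.call(rbind, seqs)
    rownames(smat) <- mem$transcript_id
    ## within-family abundance: primary 60%, pseudogenes share the rest
    npg <- nrow(mem) - 1L
    wmem <- if (npg > 0L) c(0.6, rep(0.4 / npg, npg)) else 1
    fam_w <- fam_share / length(fams)
    src[[length(src) + 1L]] <- data.frame(
      kind = "member", family = f, seq_id = mem$transcript_id,
      lo = 0L, hi = tlen - frag, strand = "+",
      weight = fam_w * wmem, class = f,
      chrom = NA, g_lo = NA, g_hi = NA, el_idx = NA,
      stringsAsFactors = FALSE)
    fam_ctx[[f]] <- list(smat = smat, targets = mem$transcript_id, tlen = tlen)
  }
  elements <- if (has_gen) genome_ann$elements else NULL
  if (!is.null(elements) && nrow(elements)) {
    el_share <- cfg$genomic_share - cfg$exon_share
    for (k in seq_len(nrow(elements))) {
      el <- elements[k, ]
      f <- el$name
      primary <- seq_to_int(as.character(db$sequences[[paste0(f, "_primary")]]))
      ## element sequence back in transcript coordinates
      plus <- substr(genome_ann$genome[[el$chrom]], el$start + 1L, el$end)
      el_seq <- if (el$strand == "+") plus else revcomp(plus)
      span <- seq.int(el$src_offset + 1L, el$src_offset + nchar(el_seq))
      evec <- rep(NA_integer_, fam_ctx[[f]]$tlen)
      evec[span] <- seq_to_int(el_seq)
      eid <- sprintf("el%02d", k)
      fam_ctx[[f]]$smat <- rbind(fam_ctx[[f]]$smat,
                                 stats::setNames(list(evec), eid)[[1L]])
      rownames(fam_ctx[[f]]$smat)[nrow(fam_ctx[[f]]$smat)] <- eid
      src[[length(src) + 1L]] <- data.frame(
        kind = "element", family = f, seq_id = eid,
        lo = el$src_offset, hi = el$src_offset + nchar(el_seq) - frag,
        strand = if (el$host_strand == el$strand) "+" else "-",
        weight = el_share / nrow(elements),
        class = if (el$host_strand == el$strand) f else antisense_family(f),
        chrom = el$chrom, g_lo = el$start, g_hi = el$end,
        el_idx = k, stringsAsFactors = FALSE)
    }
  }
  if (has_gen) {
    tx <- genome_ann$tx_db$transcripts
    exdf <- genome_ann$tx_db$exons
    ok <- exdf$end - exdf$start >= frag
    exdf <- exdf[ok, , drop = FALSE]
    m <- match(exdf$transcript_id, tx$transcript_id)
    src[[length(src) + 1L]] <- data.frame(
      kind = "exon", family = NA, seq_id = exdf$transcript_id,
      lo = exdf$start, hi = exdf$end - frag, strand = tx$strand[m],
      weight = cfg$exon_share / nrow(exdf), class = NA,
      chrom = tx$chrom[m], g_lo = tx$cds_start[m], g_hi = tx$cds_end[m],
      el_idx = NA, stringsAsFactors = FALSE)
  }
  sources <- do.call(rbind, src)
  sources$weight <- sources$weight / sum(sources$weight)
  ## difference lists source-vs-target within each family (NA positions of
  ## an element span never compared: windows stay inside the span)
  diffs <- list()
  for (f in names(fam_ctx)) {
    smat <- fam_ctx[[f]]$smat
    for (s in rownames(smat)) for (t in fam_ctx[[f]]$targets)
      diffs[[paste(s, t, sep = "\r")]] <-
        which(smat[s, ] != smat[t, ] & !is.na(smat[s, ]))
  }
  list(sources = sources, fam_ctx = fam_ctx, diffs = diffs,
       elements = elements, genome_ann = genome_ann)
}

## planted folds are target IP/input share ratios: scale specified
## families by their fold, rescale the rest to keep a distribution
apply_enrichment <- function(sources, enrichment) {
  w <- sources$weight
  spec <- rep(FALSE, nrow(sources))
  mult <- rep(1, nrow(sources))
  for (f in names(enrichment)) {
    sel <- !is.na(sources$family) & sources$family == f
    spec <- spec | sel
    mult[sel] <- enrichment[[f]]
  }
  s_spec <- sum(w[spec] * mult[spec])
  if (s_spec >= 1)
    stop("planted enrichment shares exceed 1; lower folds or family share")
  out <- w
  out[spec] <- w[spec] * mult[spec]
  out[!spec] <- w[!spec] * (1 - s_spec) / (1 - sum(w[spec]))
  out
}

## ---- read generation ----------------------------------------------------

gen_sample <- function(cfg, ctx, w, frag, tag) {
  n <- cfg$depth
  S <- ctx$sources
  si <- sample.int(nrow(S), n, replace = TRUE, prob = w)
  off <- S$lo[si] + floor(stats::runif(n) * (S$hi[si] - S$lo[si] + 1L))
  umi <- random_umis(n, cfg$umi_length)
  ## sequencing errors in fragment coordinates 1..frag
  nerr <- stats::rbinom(n, frag, cfg$per_base_error_rate)
  erow <- rep.int(seq_len(n), nerr)
  epos <- integer(0); eshift <- integer(0); eq <- integer(0)
  if (length(erow)) {
    epos <- sample.int(frag, length(erow), replace = TRUE)
    keep <- !duplicated(paste(erow, epos))
    erow <- erow[keep]; epos <- epos[keep]
    eshift <- sample.int(3L, length(erow), replace = TRUE)
    eq <- sample(c(40L, 20L), length(erow), replace = TRUE)
  }
  ## PCR duplicates: resampled parents, same coordinates/UMI/errors
  ndup <- round(cfg$duplicate_rate * n)
  if (ndup > 0L) {
    par <- sample.int(n, ndup, replace = TRUE)
    si <- c(si, si[par]); off <- c(off, off[par]); umi <- c(umi, umi[par])
    dup_sel <- erow %in% par
    ## replicate parent's errors under the duplicate's new row index
    if (any(dup_sel)) {
      map <- split(seq_len(ndup) + n, par)
      for (p in names(map)) {
        pe <- which(erow == as.integer(p))
        for (newrow in map[[p]]) {
          erow <- c(erow, rep.int(newrow, length(pe)))
          epos <- c(epos, epos[pe]); eshift <- c(eshift, eshift[pe])
          eq <- c(eq, eq[pe])
        }
      }
    }
  }
  ntot <- length(si)
  read_id <- sprintf("%s_r%07d:%s", tag, seq_len(ntot), umi)
  truth <- data.frame(read_id = read_id,
                      true_class = true_class_of(ctx, si, off, frag),
                      stringsAsFactors = FALSE)
  aln <- build_alignments(cfg, ctx, si, off, read_id, frag,
                          erow, epos, eshift, eq)
  list(aln = aln, truth = truth)
}

## truth label; for exon reads the label follows the CDS/UTR priority of
## the fragment span within its (single-exon) window
true_class_of <- function(ctx, si, off, frag) {
  S <- ctx$sources
  cls <- S$class[si]
  ex <- which(S$kind[si] == "exon")
  if (length(ex)) {
    i <- si[ex]
    fs <- off[ex]; fe <- off[ex] + frag
    cds_s <- S$g_lo[i]; cds_e <- S$g_hi[i]
    hit_cds <- fs < cds_e & fe > cds_s
    left <- fe <= cds_s; right <- fs >= cds_e
    plus <- S$strand[i] == "+"
    lab <- ifelse(hit_cds, "CDS",
           ifelse((left & plus) | (right & !plus), "5utr", "3utr"))
    cls[ex] <- lab
  }
  cls
}

## assemble every reported mapping (family members + unique genomic)
build_alignments <- function(cfg, ctx, si, off, read_id, frag,
                             erow, epos, eshift, eq) {
  S <- ctx$sources
  L <- cfg$read_length
  rows <- list()
  famish <- which(S$kind %in% c("member", "element"))
  for (srci in famish) {
    rd <- which(si == srci)
    if (!length(rd)) next
    f <- S$family[srci]
    fc <- ctx$fam_ctx[[f]]
    sid <- S$seq_id[srci]
    srow <- fc$smat[sid, ]
    for (tgt in fc$targets) {
      D <- ctx$diffs[[paste(sid, tgt, sep = "\r")]]
      w0 <- off[rd]
      lo <- findInterval(w0, D)
      hi <- findInterval(w0 + frag, D)
      cnt <- hi - lo
      ent_r <- rep.int(rd, cnt)
      ent_t <- D[sequence(cnt, from = lo + 1L)]
      ent_q <- rep.int(40L, length(ent_t))
      ## error adjustment, exact: an error reverting the base to the
      ## target's is removed; otherwise it is a mismatch at error quality
      esel <- which(erow %in% rd)
      if (length(esel)) {
        er <- erow[esel]
        et <- off[er] + epos[esel]          # transcript position (1-based)
        newb <- ((srow[et] - 1L + eshift[esel]) %% 4L) + 1L
        tgtb <- fc$smat[tgt, et]
        key <- paste(ent_r, ent_t)
        ekey <- paste(er, et)
        hitm <- match(ekey, key)
        reverts <- !is.na(hitm) & newb == tgtb
        repl <- !is.na(hitm) & newb != tgtb
        adds <- is.na(hitm) & newb != tgtb
        if (any(repl)) ent_q[hitm[repl]] <- eq[esel][repl]
        if (any(reverts)) {
          drop <- hitm[reverts]
          ent_r <- ent_r[-drop]; ent_t <- ent_t[-drop]; ent_q <- ent_q[-drop]
        }
        if (any(adds)) {
          ent_r <- c(ent_r, er[adds]); ent_t <- c(ent_t, et[adds])
          ent_q <- c(ent_q, eq[esel][adds])
        }
      }
      rows[[length(rows) + 1L]] <- pair_rows(
        read_id[rd], tgt, "family_transcript", off[rd], L,
        strand = S$strand[srci], uniq = FALSE,
        ent_row = match(ent_r, rd), ent_pos0 = ent_t - 1L, ent_q = ent_q)
    }
    ## unique genomic mapping for element-derived reads
    if (S$kind[srci] == "element") {
      el <- ctx$elements[S$el_idx[srci], ]
      w0 <- off[rd] - el$src_offset   # offset within element
      g0 <- if (el$strand == "+") el$start + w0
            else el$end - w0 - frag
      ## errors are the only genomic mismatches
      esel <- which(erow %in% rd)
      ent_r <- integer(0); ent_p <- integer(0); ent_q <- integer(0)
      if (length(esel)) {
        er <- erow[esel]
        t <- off[er] + epos[esel]
        w_el <- t - el$src_offset - 1L   # 0-based within element
        gpos <- if (el$strand == "+") el$start + w_el
                else el$end - 1L - w_el
        ent_r <- match(er, rd); ent_p <- gpos - g0[ent_r]
        ent_q <- eq[esel]
      }
      rows[[length(rows) + 1L]] <- pair_rows(
        read_id[rd], el$chrom, "genome", g0, L,
        strand = el$host_strand, uniq = TRUE,
        ent_row = ent_r, ent_pos0 = ent_p, ent_q = ent_q)
    }
  }
  exon_src <- which(S$kind == "exon")
  for (srci in exon_src) {
    rd <- which(si == srci)
    if (!length(rd)) next
    esel <- which(erow %in% rd)
    ent_r <- integer(0); ent_p <- integer(0); ent_q <- integer(0)
    if (length(esel)) {
      ent_r <- match(erow[esel], rd); ent_p <- epos[esel] - 1L
      ent_q <- eq[esel]
    }
    rows[[length(rows) + 1L]] <- pair_rows(
      read_id[rd], S$chrom[srci], "genome", off[rd], L,
      strand = S$strand[srci], uniq = TRUE,
      ent_row = ent_r, ent_pos0 = ent_p, ent_q = ent_q)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## two mate rows per pair on one target; ent_pos0 is 0-based relative to
## the fragment start on the target
pair_rows <- function(read_id, target, kind, frag_start, L, strand, uniq,
                      ent_row, ent_pos0, ent_q) {
  n <- length(read_id)
  mm <- rep(".", 2L * n)
  if (length(ent_row)) {
    mate <- ifelse(ent_pos0 < L, 1L, 2L)
    offm <- ent_pos0 - (mate - 1L) * L
    idx <- (ent_row - 1L) * 2L + mate
    str <- sprintf("%d:%d", offm, ent_q)
    o <- order(idx, offm)
    grp <- split(str[o], idx[o])
    mm[as.integer(names(grp))] <-
      vapply(grp, paste, character(1), collapse = ",")
  }
  data.frame(
    read_id = rep(read_id, each = 2L),
    mate = rep(c(1L, 2L), n),
    target_id = target,
    target_kind = kind,
    start = as.integer(rep(frag_start, each = 2L) + c(0L, L)),
    end = as.integer(rep(frag_start, each = 2L) + c(L, 2L * L)),
    strand = strand,
    mismatches = mm,
    gaps = ".",
    is_unique_genomic = uniq,
    stringsAsFactors = FALSE)
}
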