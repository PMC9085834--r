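#' Simulation configuration
#'
#' All parameters of the synthetic-data generators, validated once. The
#' defaults emulate the structure of the real inputs the pipeline consumes:
#' a multi-chromosome genome, a large point-variant background universe, an
#' ROI of ~600 unique variant positions, collections of region sets with
#' log-normal lengths (median ~1 kb) and a tunable planted enrichment, a
#' GWAS-like table carrying a small malformed/duplicate fraction so ingest
#' QC is exercised, transcript lists split at a 60-minute half-life
#' boundary, and a many-to-many ABC link table across cell types.
#'
#' @param seed Integer seed; every generator output is a pure function of
#'   the configuration including this seed.
#' @param n_chrom,chrom_length Genome model: `n_chrom` chromosomes of
#'   `chrom_length` bp each (default 5 x 10 Mb).
#' @param universe_size Number of background variant positions (default
#'   20000).
#' @param roi_size Number of trait-associated variant positions (default
#'   600).
#' @param n_sets Region sets per collection (default 20).
#' @param set_size Background regions per set (default 2000).
#' @param region_len_meanlog,region_len_sdlog Log-normal region length
#'   parameters (default median 1 kb, sdlog 0.5).
#' @param planted_or Target odds ratio of the planted set (default 1 =
#'   null; must be >= 1).
#' @param malformed_rate Fraction of malformed rows planted in the GWAS
#'   table (default 0.015).
#' @param duplicate_rate Fraction of duplicated trait rows planted in the
#'   GWAS table (default 0.005).
#' @param trait Trait code carried by ROI rows (default "EFO_0003885").
#' @param n_other_traits Number of decoy trait codes (default 4).
#' @param n_transcripts,transcript_len_meanlog,transcript_len_sdlog
#'   Transcript list size and log-normal length parameters (default 3000
#'   transcripts, median 10 kb).
#' @param short_fraction Expected fraction of transcripts with half-life
#'   below the boundary (default 0.5).
#' @param halflife_boundary Half-life split point in minutes (default 60).
#' @param n_enhancers Enhancer intervals in the ABC table (default 1000).
#' @param abc_links_mean Poisson mean of gene links per enhancer (default 2).
#' @param abc_score_shape1,abc_score_shape2 Beta parameters of ABC scores
#'   (default 1.5, 30 — small scores with a thin right tail, as ABC
#'   predictions look in practice).
#' @param n_genes Gene catalog size (default 500).
#' @param n_cell_types Cell-type labels used in the ABC table (default 5).
#' @return A validated `sim_config` object (a list).
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 5L, chrom_length = 10e6,
                       universe_size = 20000L, roi_size = 600L,
                       n_sets = 20L, set_size = 2000L,
                       region_len_meanlog = log(1000),
                       region_len_sdlog = 0.5,
                       planted_or = 1,
                       malformed_rate = 0.015, duplicate_rate = 0.005,
                       trait = "EFO_0003885", n_other_traits = 4L,
                       n_transcripts = 3000L,
                       transcript_len_meanlog = log(10000),
                       transcript_len_sdlog = 0.8,
                       short_fraction = 0.5, halflife_boundary = 60,
                       n_enhancers = 1000L, abc_links_mean = 2,
                       abc_score_shape1 = 1.5, abc_score_shape2 = 30,
                       n_genes = 500L, n_cell_types = 5L) {
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_length = chrom_length,
              universe_size = as.integer(universe_size),
              roi_size = as.integer(roi_size),
              n_sets = as.integer(n_sets), set_size = as.integer(set_size),
              region_len_meanlog = region_len_meanlog,
              region_len_sdlog = region_len_sdlog,
              planted_or = planted_or,
              malformed_rate = malformed_rate,
              duplicate_rate = duplicate_rate,
              trait = trait, n_other_traits = as.integer(n_other_traits),
              n_transcripts = as.integer(n_transcripts),
              transcript_len_meanlog = transcript_len_meanlog,
              transcript_len_sdlog = transcript_len_sdlog,
              short_fraction = short_fraction,
              halflife_boundary = halflife_boundary,
              n_enhancers = as.integer(n_enhancers),
              abc_links_mean = abc_links_mean,
              abc_score_shape1 = abc_score_shape1,
              abc_score_shape2 = abc_score_shape2,
              n_genes = as.integer(n_genes),
              n_cell_types = as.integer(n_cell_types))
  counts <- c(cfg$n_chrom, cfg$chrom_length, cfg$universe_size,
              cfg$roi_size, cfg$n_sets, cfg$set_size, cfg$n_transcripts,
              cfg$n_enhancers, cfg$n_genes, cfg$n_cell_types)
  if (anyNA(counts) || any(counts < 1)) stop("all counts must be positive")
  if (cfg$roi_size > cfg$universe_size) {
    stop("roi_size cannot exceed universe_size")
  }
  if (cfg$planted_or < 0) stop("planted_or must be >= 0")
  fracs <- c(cfg$malformed_rate, cfg$duplicate_rate, cfg$short_fraction)
  if (any(fracs < 0) || any(fracs > 1)) {
    stop("rates and fractions must lie in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

# Seqinfo construction is comparatively costly; the model depends only on
# the genome dimensions, so cache it across generator calls
.sim_genome_cache <- new.env(parent = emptyenv())

sim_genome <- function(config) {
  key <- paste(config$n_chrom, config$chrom_length)
  cached <- .sim_genome_cache[[key]]
  if (!is.null(cached)) return(cached)
  gm <- genome_model(paste0("chr", seq_len(config$n_chrom)),
                     rep(config$chrom_length, config$n_chrom))
  .sim_genome_cache[[key]] <- gm
  gm
}

# length-weighted chromosome draw + uniform position (1-based)
draw_points <- function(n, genome) {
  chroms <- GenomeInfoDb::seqnames(genome)
  lens <- as.numeric(GenomeInfoDb::seqlengths(genome))
  idx <- sample.int(length(chroms), n, replace = TRUE, prob = lens)
  pos <- floor(stats::runif(n) * lens[idx]) + 1
  data.table::data.table(chrom = chroms[idx], pos = as.integer(pos))
}

#' Simulate the variant universe, ROI and GWAS-like table
#'
#' Universe positions are uniform over the genome; the ROI is a random
#' subset of the universe. The emitted GWAS-like record table carries the
#' configured malformed rows (unintelligible coordinates) and duplicated
#' trait rows so [build_roi()] QC is exercised; the returned `universe` and
#' `roi` sets are themselves built through [build_universe()] and
#' [build_roi()] from that table. Deterministic under the config seed.
#'
#' @param config A [sim_config()] object.
#' @return A list: `genome`, `records` (the GWAS-like table), `universe`,
#'   `roi`, `qc` (the [build_roi()] QC report) and `truth`
#'   (`n_malformed`, `n_duplicate`, planted sizes).
#' @export
simulate_universe_and_roi <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- sim_genome(config)
  withr::with_seed(config$seed, {
    pts <- draw_points(config$universe_size * 1.05 + 10, genome)
    pts <- pts[!duplicated(paste(chrom, pos))][seq_len(config$universe_size)]
    if (anyNA(pts$chrom)) stop("could not draw enough unique positions")
    roi_idx <- sort(sample.int(config$universe_size, config$roi_size))
    is_roi <- seq_len(config$universe_size) %in% roi_idx
    other_traits <- paste0("EFO_", sprintf("%07d", seq_len(config$n_other_traits)))
    rec <- data.table::data.table(
      snp = paste0("rs", seq_len(config$universe_size)),
      chrom = pts$chrom,
      pos_raw = as.character(pts$pos),
      trait = ifelse(is_roi, config$trait,
                     sample(other_traits, config$universe_size, replace = TRUE)),
      gene = paste0("GENE", seq_len(config$universe_size)),
      study = "GCST000001"
    )
    n_dup <- round(config$duplicate_rate * config$roi_size)
    n_mal <- round(config$malformed_rate * config$roi_size)
    extra <- list()
    if (n_dup > 0) {
      src <- rec[which(is_roi)][sample.int(config$roi_size, n_dup)]
      src[, snp := paste0(snp, "_dup")]
      extra <- c(extra, list(src))
    }
    if (n_mal > 0) {
      extra <- c(extra, list(data.table::data.table(
        snp = paste0("rs_bad", seq_len(n_mal)),
        chrom = "NR", pos_raw = "-",
        trait = config$trait, gene = "intergenic", study = "GCST000001"
      )))
    }
    records <- data.table::rbindlist(c(list(rec), extra), use.names = TRUE)
    records <- records[sample.int(nrow(records))]
  })
  built <- build_roi(records, config$trait, genome)
  universe <- build_universe(records, genome)
  list(genome = genome, records = records, universe = universe,
       roi = built$roi, qc = built$qc,
       truth = list(n_malformed = n_mal, n_duplicate = n_dup,
                    roi_size = config$roi_size,
                    universe_size = config$universe_size))
}

# one background region set: uniform placement, log-normal lengths
draw_region_set <- function(n, config, genome, label) {
  chroms <- GenomeInfoDb::seqnames(genome)
  lens <- as.numeric(GenomeInfoDb::seqlengths(genome))
  idx <- sample.int(length(chroms), n, replace = TRUE, prob = lens)
  len <- pmax(1, round(stats::rlnorm(n, config$region_len_meanlog,
                                     config$region_len_sdlog)))
  len <- pmin(len, lens[idx])
  start <- floor(stats::runif(n) * (lens[idx] - len + 1))
  region_set(chroms[idx], start, start + len, genome = genome, label = label)
}

#' Simulate a region collection with one planted-enriched set
#'
#' Null sets are placed uniformly, independent of the ROI. The planted set
#' receives, on top of its own uniform background, regions covering a
#' Bernoulli-selected fraction of ROI positions, with the selection
#' probability tuned so the expected 2x2 odds ratio against the universe
#' equals `planted_or`: if `p0` is the background per-point hit probability
#' (`1 - prod(1 - len_i/G)` from the drawn background lengths) the target
#' ROI hit probability `p1` solves `odds(p1) = planted_or * odds(p0)` and
#' the selection probability is `(p1 - p0) / (1 - p0)`. A `planted_or`
#' below 1 is infeasible under this additive-coverage scheme and errors.
#'
#' @param config A [sim_config()] object.
#' @param sim Output of [simulate_universe_and_roi()] (provides genome,
#'   universe and ROI).
#' @param planted_or Target odds ratio (default `config$planted_or`).
#' @param n_sets Number of sets (default `config$n_sets`).
#' @return A list: `collection` (`RegionCollection`) and `truth`
#'   (`planted_label`, `planted_or`, `p0`, `pi`).
#' @export
simulate_collection <- function(config, sim,
                                planted_or = config$planted_or,
                                n_sets = config$n_sets) {
  stopifnot(inherits(config, "sim_config"))
  genome <- sim$genome
  G <- genome_size(genome)
  roi_df <- as.data.frame(sim$roi)
  withr::with_seed(config$seed + 1L, {
    labels <- sprintf("set_%02d", seq_len(n_sets))
    planted_idx <- sample.int(n_sets, 1L)
    sets <- vector("list", n_sets)
    truth <- NULL
    for (i in seq_len(n_sets)) {
      bg <- draw_region_set(config$set_size, config, genome, labels[i])
      if (i != planted_idx || planted_or == 1) {
        sets[[i]] <- bg
        if (i == planted_idx) {
          truth <- list(planted_label = labels[i], planted_or = planted_or,
                        p0 = NA_real_, pi = 0)
        }
        next
      }
      bg_df <- as.data.frame(bg)
      p0 <- 1 - prod(1 - (bg_df$end - bg_df$start) / G)
      odds0 <- p0 / (1 - p0)
      odds1 <- planted_or * odds0
      p1 <- odds1 / (1 + odds1)
      pi <- (p1 - p0) / (1 - p0)
      if (planted_or < 1 || pi < 0) {
        stop(sprintf(
          "planted odds ratio %.3g infeasible under additive coverage; feasible range is [1, Inf)",
          planted_or))
      }
      sel <- which(stats::runif(nrow(roi_df)) < pi)
      if (length(sel) > 0L) {
        len <- pmax(1, round(stats::rlnorm(length(sel),
                                           config$region_len_meanlog,
                                           config$region_len_sdlog)))
        lens <- GenomeInfoDb::seqlengths(genome)[roi_df$chrom[sel]]
        len <- pmin(len, as.numeric(lens))
        point <- roi_df$start[sel] # 0-based position to cover
        offset <- floor(stats::runif(length(sel)) * len)
        start <- point - offset
        start <- pmax(0, pmin(start, as.numeric(lens) - len))
        start <- pmax(pmin(start, point), point - len + 1)
        start <- pmax(0, start)
        tgt_chrom <- roi_df$chrom[sel]
        all_chrom <- c(bg_df$chrom, tgt_chrom)
        all_start <- c(bg_df$start, start)
        all_end <- c(bg_df$end, pmin(start + len, as.numeric(lens)))
        sets[[i]] <- region_set(all_chrom, all_start, all_end,
                                genome = genome, label = labels[i])
      } else {
        sets[[i]] <- bg
      }
      truth <- list(planted_label = labels[i], planted_or = planted_or,
                    p0 = p0, pi = pi)
    }
  })
  list(collection = region_collection(sets), truth = truth)
}

#' Split transcript intervals by half-life
#'
#' Exhaustive, disjoint partition of transcripts at the half-life boundary:
#' "short" strictly below the boundary, "long" at or above it.
#'
#' @param regions `RegionSet` of transcript intervals.
#' @param halflives Numeric vector of half-lives in minutes, one per
#'   interval.
#' @param boundary Split point in minutes (default 60).
#' @return A `RegionCollection` with sets `short_halflife` and
#'   `long_halflife`.
#' @export
split_by_halflife <- function(regions, halflives, boundary = 60) {
  stopifnot(inherits(regions, "RegionSet"))
  if (length(halflives) != length(regions)) {
    stop("one half-life per transcript required")
  }
  df <- as.data.frame(regions)
  genome <- rs_genome(regions)
  short <- halflives < boundary
  mk <- function(keep, label) {
    region_set(df$chrom[keep], df$start[keep], df$end[keep],
               name = df$name[keep], genome = genome, label = label)
  }
  region_collection(list(mk(short, "short_halflife"),
                         mk(!short, "long_halflife")))
}

#' Simulate transcript lists with half-life labels
#'
#' Transcript intervals with exponential half-life draws, partitioned at
#' the configured boundary (default 60 minutes) into short/long lists. The
#' exponential mean is set so the expected short fraction matches
#' `config$short_fraction`.
#'
#' @param config A [sim_config()] object.
#' @param genome A `Seqinfo` genome model.
#' @return A list: `collection` (short/long `RegionCollection`) and
#'   `halflives` (the drawn values, transcript order).
#' @export
simulate_transcript_lists <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  sf <- config$short_fraction
  withr::with_seed(config$seed + 2L, {
    tx_cfg <- config
    tx_cfg$region_len_meanlog <- config$transcript_len_meanlog
    tx_cfg$region_len_sdlog <- config$transcript_len_sdlog
    tx <- draw_region_set(config$n_transcripts, tx_cfg, genome, "transcripts")
    df <- as.data.frame(tx)
    tx <- region_set(df$chrom, df$start, df$end,
                     name = paste0("tx", seq_len(nrow(df))),
                     genome = genome, label = "transcripts")
    if (sf <= 0) {
      halflives <- rep(config$halflife_boundary + 1, config$n_transcripts)
    } else if (sf >= 1) {
      halflives <- rep(config$halflife_boundary / 2, config$n_transcripts)
    } else {
      mean_hl <- -config$halflife_boundary / log(1 - sf)
      halflives <- stats::rexp(config$n_transcripts, rate = 1 / mean_hl)
    }
  })
  list(collection = split_by_halflife(tx, halflives,
                                      config$halflife_boundary),
       halflives = halflives)
}

#' Simulate a precomputed ABC enhancer-gene link table
#'
#' Enhancer intervals with Poisson-many gene links each, Beta-distributed
#' ABC scores in `[0, 1]`, genes drawn from a synthetic catalog and cell
#' types from a small label set. Returned in the published ABC output table
#' dialect (`chr`, `start`, `end`, `TargetGene`, `ABC.Score`, `CellType`).
#'
#' @param config A [sim_config()] object.
#' @param genome A `Seqinfo` genome model.
#' @return A `data.table` in ABC dialect, one row per link.
#' @export
simulate_abc_table <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  cells <- c("B_cell", "T_cell", "monocyte", "microglia", "NK_cell",
             "dendritic", "epithelial", "neuron")[seq_len(config$n_cell_types)]
  withr::with_seed(config$seed + 3L, {
    enh_cfg <- config
    enh_cfg$region_len_meanlog <- log(500)
    enh_cfg$region_len_sdlog <- 0.4
    enh <- as.data.frame(draw_region_set(config$n_enhancers, enh_cfg,
                                         genome, "enhancers"))
    n_links <- stats::rpois(config$n_enhancers, config$abc_links_mean)
    idx <- rep(seq_len(config$n_enhancers), n_links)
    total <- length(idx)
    tbl <- data.table::data.table(
      chr = enh$chrom[idx],
      start = enh$start[idx],
      end = enh$end[idx],
      TargetGene = sprintf("G%04d", sample.int(config$n_genes, total,
                                               replace = TRUE)),
      ABC.Score = stats::rbeta(total, config$abc_score_shape1,
                               config$abc_score_shape2),
      CellType = sample(cells, total, replace = TRUE)
    )
  })
  tbl[]
}

#' Simulate DBR sets for a panel of molecular transducers
#'
#' One region set per transducer, each an independent mixture of uniform
#' background regions and regions covering a Bernoulli-selected fraction of
#' ROI positions (the per-transducer binding probability). Gives the
#' multi-transducer membership analysis a known co-binding structure:
#' under independence, a variant binds `k` transducers with Poisson-binomial
#' probability.
#'
#' @param config A [sim_config()] object.
#' @param sim Output of [simulate_universe_and_roi()].
#' @param bind_prob Named numeric vector: per-transducer probability that an
#'   ROI variant is covered by a targeted region (defaults to a
#'   VDR/AID/EBNA2/EBNA3C-like panel).
#' @param set_size Background regions per DBR set (default
#'   `config$set_size / 2`).
#' @return A list: `dbrs` (`RegionCollection`) and `truth` (`bind_prob`).
#' @export
simulate_dbr_sets <- function(config, sim,
                              bind_prob = c(VDR = 0.40, AID = 0.20,
                                            EBNA2 = 0.30, EBNA3C = 0.10),
                              set_size = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(names(bind_prob)) || any(!nzchar(names(bind_prob)))) {
    stop("bind_prob must be a named vector")
  }
  if (any(bind_prob < 0) || any(bind_prob > 1)) {
    stop("binding probabilities must lie in [0, 1]")
  }
  if (is.null(set_size)) set_size <- max(1L, config$set_size %/% 2L)
  genome <- sim$genome
  roi_df <- as.data.frame(sim$roi)
  withr::with_seed(config$seed + 4L, {
    sets <- lapply(names(bind_prob), function(lab) {
      bg <- as.data.frame(draw_region_set(set_size, config, genome, lab))
      sel <- which(stats::runif(nrow(roi_df)) < bind_prob[[lab]])
      if (length(sel) == 0L) {
        return(region_set(bg$chrom, bg$start, bg$end, genome = genome,
                          label = lab))
      }
      len <- pmax(1, round(stats::rlnorm(length(sel),
                                         config$region_len_meanlog,
                                         config$region_len_sdlog)))
      lens <- as.numeric(GenomeInfoDb::seqlengths(genome)[roi_df$chrom[sel]])
      len <- pmin(len, lens)
      point <- roi_df$start[sel]
      offset <- floor(stats::runif(length(sel)) * len)
      start <- pmax(0, pmin(point - offset, lens - len))
      start <- pmax(0, pmax(pmin(start, point), point - len + 1))
      region_set(c(bg$chrom, roi_df$chrom[sel]),
                 c(bg$start, start),
                 c(bg$end, pmin(start + len, lens)),
                 genome = genome, label = lab)
    })
  })
  list(dbrs = region_collection(sets), truth = list(bind_prob = bind_prob))
}

#' Simulate a GMT gene-set collection over the synthetic gene catalog
#'
#' Random gene sets drawn from the same catalog the ABC generator uses, so
#' the gene-set enrichment stage of the pipeline has an input. Not a
#' statistical null model with planted pathway signal — a structural
#' stand-in only.
#'
#' @param config A [sim_config()] object.
#' @param n_gene_sets Number of sets (default 15).
#' @param set_size_range Integer range of genes per set (default 10–50).
#' @return A `GeneSetCollection` with `background = config$n_genes`.
#' @export
simulate_gene_sets <- function(config, n_gene_sets = 15L,
                               set_size_range = c(10L, 50L)) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 5L, {
    sets <- lapply(seq_len(n_gene_sets), function(i) {
      sz <- sample(seq(set_size_range[1L], set_size_range[2L]), 1L)
      sprintf("G%04d", sample.int(config$n_genes, min(sz, config$n_genes)))
    })
    names(sets) <- sprintf("pathway_%02d", seq_len(n_gene_sets))
  })
  gene_set_collection(sets, background = config$n_genes)
}
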