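#' Generate a toy circular mitochondrial genome
#'
#' Builds a small random circular genome with non-overlapping CDS, tRNA and
#' rRNA features on both strands, valid under the vertebrate mitochondrial
#' code (ATG start, no internal stops, TAA stop).  Deterministic under
#' `seed`.  Intended for tests and examples; real analyses read the rCRS
#' from FASTA.
#'
#' @param seed integer seed.
#' @param n_genes number of CDS features, default 3.
#' @param length genome length in bp (>= 300), default 1,200.
#' @return an [mt_genome]; the D-loop and origin regions wrap the
#'   coordinate origin, scaled to the toy length.
#' @export
generate_toy_genome <- function(seed = 1L, n_genes = 3L, length = 1200L) {
  if (length < 300L) stop("toy genome length must be >= 300")
  set.seed(seed)
  L <- as.integer(length)
  s <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
              prob = c(0.31, 0.31, 0.13, 0.25)) # rCRS-like light strand
  stops <- c("TAA", "TAG", "AGA", "AGG")
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense_codons <- setdiff(all_codons, stops)

  # reserve: genes side by side with spacers; sizes chosen to fit
  spacer <- 30L
  reserved <- 120L + 2L * spacer          # tRNA + rRNA features
  avail <- L - reserved - (n_genes + 1L) * spacer - 60L # keep origin clear
  codons_per_gene <- max(4L, (avail %/% n_genes) %/% 3L - 2L)
  if (codons_per_gene < 4L) stop("genome too short to pack ", n_genes, " genes")
  ann <- list()
  cursor <- 61L # leave the wrapped control region free
  for (i in seq_len(n_genes)) {
    n_codon <- codons_per_gene
    cds <- c("ATG", sample(sense_codons, n_codon - 2L, replace = TRUE), "TAA")
    cds_seq <- paste(cds, collapse = "")
    strand <- if (i %% 2L == 0L) "-" else "+"
    ins <- if (strand == "+") cds_seq else revcomp(cds_seq)
    start <- cursor
    end <- start + nchar(ins) - 1L
    if (end > L - reserved - 60L) stop("infeasible gene packing")
    s[start:end] <- strsplit(ins, "")[[1]]
    ann[[length(ann) + 1L]] <- data.frame(
      name = paste0("TOYG", i), start = start, end = end, strand = strand,
      feature = "CDS", stringsAsFactors = FALSE)
    cursor <- end + spacer + 1L
  }
  ann[[length(ann) + 1L]] <- data.frame(
    name = "TOY-tRNA1", start = cursor, end = cursor + 39L, strand = "+",
    feature = "tRNA", stringsAsFactors = FALSE)
  cursor <- cursor + 40L + spacer
  ann[[length(ann) + 1L]] <- data.frame(
    name = "TOY-rRNA1", start = cursor, end = cursor + 79L, strand = "+",
    feature = "rRNA", stringsAsFactors = FALSE)
  mt_genome(paste(s, collapse = ""), do.call(rbind, ann),
            dloop = c(L - 45L, 35L), origin_region = c(L - 25L, 15L))
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the published study conditions: three tissue types with
#' mitotic turnover rates of 14.3 (colon), 20.8 (fibroblast) and 17.9
#' (HSPC) turnovers per year, a mutation rate of 5e-8 per bp per
#' replication, ~750 mtDNA copies per cell, mean mtDNA depth ~6,000x with
#' a lognormal spread, about two fertilized-egg heteroplasmies per donor,
#' and a small set of hypermutable hotspot loci recurring across donors.
#'
#' @param donors data.frame with `donor_id`, `tissue`, `age`, `n_clones`;
#'   default is a compact three-tissue cohort.
#' @param model turnover model used for the drift of true frequencies.
#' @param turnover_rates named per-tissue turnover rates per year.
#' @param r mutation rate per bp per replication.
#' @param copy_number basal mtDNA copies per cell.
#' @param depth_mean,depth_sdlog lognormal per-clone mtDNA depth model.
#' @param n_hetfe_per_donor fertilized-egg variants per donor.
#' @param egg_vaf_range log-uniform support of egg VAFs.
#' @param n_hotspots,hotspot_prob hotspot loci and per-clone occurrence
#'   probability.
#' @param rate_genome_length genome length multiplying `r` into the
#'   per-replication mutation intensity, default 16,569 (rCRS).  Toy
#'   genomes only provide the coordinate space for variant placement; the
#'   mutation burden stays at the human-mtDNA scale.
#' @param n_noise_sites pure-noise loci carried in the measurements.
#' @param noise_low,noise_high,noise_elevated_frac two-component per-locus
#'   error-rate mixture (mean low/high rates, elevated fraction).
#' @param detection_floor observed-VAF calling floor (~0.3\%).
#' @return list of class `mt_cohort_config`.
#' @export
cohort_config <- function(donors = NULL,
                          model = c("mitotic", "homeostatic"),
                          turnover_rates = c(colon = 14.3, fibroblast = 20.8,
                                             HSPC = 17.9),
                          r = 5e-8, copy_number = 750L,
                          rate_genome_length = 16569L,
                          depth_mean = 6000, depth_sdlog = 0.5,
                          n_hetfe_per_donor = 2L,
                          egg_vaf_range = c(0.005, 0.5),
                          n_hotspots = 3L, hotspot_prob = 0.01,
                          n_noise_sites = 30L,
                          noise_low = 1e-4, noise_high = 2e-3,
                          noise_elevated_frac = 0.05,
                          detection_floor = 0.003) {
  model <- match.arg(model)
  if (is.null(donors)) {
    donors <- data.frame(
      donor_id = sprintf("D%02d", 1:6),
      tissue = rep(c("colon", "fibroblast", "HSPC"), each = 2L),
      age = c(48, 81, 30, 75, 35, 60),
      n_clones = rep(25L, 6L),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("donor_id", "tissue", "age", "n_clones") %in% names(donors)))
  if (any(donors$n_clones < 1L)) stop("every donor needs at least one clone")
  structure(list(donors = donors, model = model,
                 turnover_rates = turnover_rates, r = r,
                 copy_number = as.integer(copy_number),
                 rate_genome_length = as.integer(rate_genome_length),
                 depth_mean = depth_mean, depth_sdlog = depth_sdlog,
                 n_hetfe_per_donor = as.integer(n_hetfe_per_donor),
                 egg_vaf_range = egg_vaf_range,
                 n_hotspots = as.integer(n_hotspots),
                 hotspot_prob = hotspot_prob,
                 n_noise_sites = as.integer(n_noise_sites),
                 noise_low = noise_low, noise_high = noise_high,
                 noise_elevated_frac = noise_elevated_frac,
                 detection_floor = detection_floor),
            class = "mt_cohort_config")
}

# random site on the genome avoiding previously used positions
draw_sites <- function(genome, k, used) {
  if (k == 0L)
    return(data.frame(position = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE))
  pos <- sample(setdiff(seq_len(genome$length), used), k)
  ref <- substring(genome$sequence, pos, pos)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                character(1))
  data.frame(position = pos, ref = ref, alt = unname(alt),
             stringsAsFactors = FALSE)
}

#' Generate a truth-labelled synthetic cohort
#'
#' Per donor, fertilized-egg (Het_FE) variants drift for
#' `turnover_rate * age` turnovers under the configured model; PZ_simple
#' mutations accumulate via the molecule-tracking simulator at rate `r`;
#' hotspot loci recur across donors; observed alt counts are drawn
#' binomially from the true frequency plus per-locus background error at a
#' lognormal per-clone depth; a donor phylogeny with an early first split
#' is attached, and matched bulk VAFs are emitted for Het_FE variants.
#'
#' @param config an [cohort_config()].
#' @param genome an [mt_genome]; default `generate_toy_genome(seed, length
#'   = 2000, n_genes = 4)`.
#' @param seed integer seed.
#' @param dir optional directory: when given, all files are written in the
#'   formats [load_cohort()] reads (plus `truth.tsv`).
#' @return list of class `mt_synth_cohort` with `cohort` (an `mt_cohort`),
#'   `truth` (per-(variant, clone) true frequencies and classes), `genome`,
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config(), genome = NULL,
                            seed = 1L, dir = NULL) {
  stopifnot(inherits(config, "mt_cohort_config"))
  set.seed(seed)
  if (is.null(genome))
    genome <- generate_toy_genome(seed = seed + 1L, n_genes = 4L,
                                  length = 2000L)
  set.seed(seed) # toy-genome generation must not perturb the cohort stream
  donors <- config$donors
  n_total <- sum(donors$n_clones)
  cn <- config$copy_number
  lambda <- config$r * config$rate_genome_length

  meta <- do.call(rbind, lapply(seq_len(nrow(donors)), function(i) {
    nc <- donors$n_clones[i]
    data.frame(clone_id = sprintf("%s_c%03d", donors$donor_id[i], seq_len(nc)),
               donor_id = donors$donor_id[i], tissue = donors$tissue[i],
               donor_age = donors$age[i],
               mean_coverage_nuclear = round(runif(nc, 15, 45), 2),
               mean_coverage_mt = NA_real_,
               nuclear_clonality_vaf = round(runif(nc, 0.42, 0.5), 3),
               stringsAsFactors = FALSE)
  }))
  # per-clone copy number lognormal around the basal value; mt coverage
  # follows from copy number and nuclear coverage
  clone_cn <- pmax(50, rlnorm(n_total, log(cn), 0.25))
  meta$mean_coverage_mt <- round(clone_cn / 2 * meta$mean_coverage_nuclear, 1)
  depth <- pmax(200, round(rlnorm(n_total, log(config$depth_mean),
                                  config$depth_sdlog)))
  names(depth) <- meta$clone_id

  used <- integer(0)
  truth <- list()
  site_rows <- list() # true per-clone frequencies at each truth site
  add_truth <- function(site, donor, clones, freqs, class, egg_vaf = NA_real_) {
    truth[[length(truth) + 1L]] <<- data.frame(
      position = site$position, ref = site$ref, alt = site$alt,
      donor_id = donor, clone_id = clones, true_freq = freqs,
      true_class = class, egg_vaf = egg_vaf, stringsAsFactors = FALSE)
  }

  hot_sites <- NULL
  if (config$n_hotspots > 0L) {
    hot_sites <- draw_sites(genome, config$n_hotspots, used)
    used <- c(used, hot_sites$position)
  }

  for (i in seq_len(nrow(donors))) {
    d <- donors$donor_id[i]
    clones <- meta$clone_id[meta$donor_id == d]
    nc <- length(clones)
    g <- as.integer(round(config$turnover_rates[[donors$tissue[i]]] *
                            donors$age[i]))
    # Het_FE variants: independent drift per variant across clone lineages
    if (config$n_hetfe_per_donor > 0L) {
      sites <- draw_sites(genome, config$n_hetfe_per_donor, used)
      used <- c(used, sites$position)
      for (j in seq_len(nrow(sites))) {
        egg <- exp(runif(1, log(config$egg_vaf_range[1]),
                         log(config$egg_vaf_range[2])))
        if (g > 0L) {
          k0 <- rep.int(as.integer(round(egg * cn)), nc)
          k0 <- pmax(1L, k0) # detectable egg variants span >= 1 molecule
          res <- cpp_drift_two_allele(k0, cn, g,
                                      if (config$model == "mitotic") 0L else 1L,
                                      integer(0), cn)
          fr <- res$k_final / cn
        } else fr <- rep(max(egg, 1 / cn), nc)
        add_truth(sites[j, ], d, clones, fr, "Het_FE", egg)
      }
    }
    # PZ_simple mutations: molecule-tracking accumulation per clone lineage
    if (config$r > 0 && g > 0L) {
      ms <- cpp_lineage_sim(cn, nc, g, lambda,
                            if (config$model == "mitotic") 0L else 1L,
                            integer(0), FALSE, TRUE, cn)
      for (ci in seq_len(nc)) {
        fr <- ms$final_muts[[ci]]
        fr <- fr[fr >= 1e-4] # drop effectively extinct mutations
        if (!length(fr)) next
        sites <- draw_sites(genome, length(fr), used)
        used <- c(used, sites$position)
        for (j in seq_len(nrow(sites)))
          add_truth(sites[j, ], d, clones[ci], fr[j], "PZ_simple")
      }
    }
    # hotspot recurrences
    if (!is.null(hot_sites)) {
      for (j in seq_len(nrow(hot_sites))) {
        hit <- runif(nc) < config$hotspot_prob
        if (any(hit))
          add_truth(hot_sites[j, ], d, clones[hit],
                    rbeta(sum(hit), 0.4, 2), "PZ_recurrent")
      }
    }
  }
  truth <- do.call(rbind, truth)

  # noise-only sites; the elevated error component lives on noise-only loci
  # so that truth labels stay identifiable (hotspots model recurrence)
  noise_sites <- draw_sites(genome, config$n_noise_sites, used)
  all_sites <- unique(rbind(truth[, c("position", "ref", "alt")],
                            noise_sites))
  is_noise_only <- !(variant_key(all_sites) %in% variant_key(truth))
  elevated <- is_noise_only &
    runif(nrow(all_sites)) < config$noise_elevated_frac
  err_rate <- ifelse(elevated,
                     stats::rexp(nrow(all_sites), 1 / config$noise_high),
                     stats::rexp(nrow(all_sites), 1 / config$noise_low))
  names(err_rate) <- variant_key(all_sites)

  # measurements: every clone x every site
  tk <- variant_key(truth)
  mm <- do.call(rbind, lapply(seq_len(nrow(all_sites)), function(si) {
    k <- variant_key(all_sites[si, ])
    tf <- setNames(rep(0, n_total), meta$clone_id)
    sel <- tk == k
    if (any(sel)) tf[truth$clone_id[sel]] <- truth$true_freq[sel]
    p <- pmin(1, tf + err_rate[[k]])
    alt_n <- rbinom(n_total, depth, p)
    data.frame(clone_id = meta$clone_id,
               position = all_sites$position[si],
               ref = all_sites$ref[si], alt = all_sites$alt[si],
               vaf = alt_n / depth, alt_count = alt_n,
               depth = unname(depth), stringsAsFactors = FALSE)
  }))
  mm$called <- mm$vaf > config$detection_floor
  mm <- mm[order(mm$position, mm$clone_id), , drop = FALSE]
  rownames(mm) <- NULL

  # phylogenies: internal splits carry early-embryonic mutation counts (a
  # few nuclear mutations per division), terminal branches the lifetime
  # somatic burden; clone divergence is therefore early, as in polyclonal
  # tissues
  phylo <- setNames(lapply(seq_len(nrow(donors)), function(i) {
    clones <- meta$clone_id[meta$donor_id == donors$donor_id[i]]
    if (length(clones) < 2L) return(NULL)
    tr <- ape::rtree(length(clones), tip.label = sample(clones))
    terminal <- tr$edge[, 2L] <= ape::Ntip(tr)
    tr$edge.length[terminal] <- runif(sum(terminal), 300, 1500)
    tr$edge.length[!terminal] <- runif(sum(!terminal), 1, 6)
    tr
  }), donors$donor_id)
  phylo <- phylo[!vapply(phylo, is.null, logical(1))]

  # matched bulk tissue: Het_FE variants at ~egg VAF
  hf <- truth[truth$true_class == "Het_FE", , drop = FALSE]
  bulk <- NULL
  if (nrow(hf)) {
    uh <- unique(hf[, c("position", "ref", "alt", "donor_id", "egg_vaf")])
    bdepth <- 3000L
    bulk <- data.frame(donor_id = uh$donor_id,
                       tissue = "blood",
                       position = uh$position, ref = uh$ref, alt = uh$alt,
                       vaf = rbinom(nrow(uh), bdepth, uh$egg_vaf) / bdepth,
                       stringsAsFactors = FALSE)
  }

  cohort <- structure(list(clones = meta, measurements = mm,
                           calls = mm[mm$called, , drop = FALSE],
                           phylo = phylo, bulk = bulk),
                      class = "mt_cohort")
  out <- structure(list(cohort = cohort, truth = truth, genome = genome,
                        config = config, err_rate = err_rate,
                        clone_copy_number = setNames(clone_cn, meta$clone_id)),
                   class = "mt_synth_cohort")
  if (!is.null(dir)) {
    write_cohort(cohort, dir)
    write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_mt_genome(genome, file.path(dir, "genome.fa"),
                    file.path(dir, "genes.tsv"))
  }
  out
}

#' @export
print.mt_synth_cohort <- function(x, ...) {
  cat("mt_synth_cohort:", nrow(x$cohort$clones), "clones,",
      nrow(unique(x$truth[, c("position", "ref", "alt")])), "truth sites\n")
  print(table(unique(x$truth[, c("position", "ref", "alt",
                                 "true_class")])$true_class))
  invisible(x)
}

#' Generate read-support summaries with planned QC violations
#'
#' Produces one [apply_read_filters()] input row per plan entry whose
#' summaries violate exactly the planned reason codes and nothing else.
#' Positions must be consistent with positional codes (`blacklist`,
#' `indel_locus`): a plan naming them at a clean position — or omitting
#' them at a blacklisted position — is contradictory and errors.
#'
#' @param plan data.frame with `position`, `variant_type`, `violations`
#'   (semicolon-separated reason codes, empty string = all pass).
#' @param seed integer seed (jitters the clean values).
#' @return data.frame accepted by [apply_read_filters()].
#' @export
generate_read_support <- function(plan, seed = 1L) {
  set.seed(seed)
  th <- mt_filter_thresholds()
  n <- nrow(plan)
  in_bl <- rep(FALSE, n)
  for (r in seq_len(nrow(th$blacklist)))
    in_bl <- in_bl | (plan$position >= th$blacklist[r, 1] &
                      plan$position <= th$blacklist[r, 2])
  is_indel <- plan$variant_type %in% c("insertion", "deletion")
  in_il <- is_indel & plan$position %in% th$indel_blacklist
  out <- data.frame(position = plan$position,
                    variant_type = plan$variant_type,
                    mean_mapq = runif(n, 40, 60),
                    mean_baseq = runif(n, 25, 35),
                    mean_position_fraction = runif(n, 0.3, 0.7),
                    forward_fraction = runif(n, 0.4, 0.6),
                    max_mismatches = sample(0:3, n, replace = TRUE),
                    pairing_ok = TRUE,
                    frac_additional_indels = ifelse(is_indel,
                                                    runif(n, 0, 0.3), NA),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    v <- strsplit(plan$violations[i], ";")[[1]]
    v <- v[nzchar(v)]
    if (("blacklist" %in% v) != in_bl[i])
      stop("plan row ", i, ": blacklist violation inconsistent with position")
    if (("indel_locus" %in% v) != in_il[i])
      stop("plan row ", i, ": indel_locus violation inconsistent with position/type")
    if (any(c("indel_noise") %in% v) && !is_indel[i])
      stop("plan row ", i, ": indel_noise planned for an SNV")
    if ("mapq" %in% v) out$mean_mapq[i] <- runif(1, 5, 20)
    if ("baseq" %in% v) out$mean_baseq[i] <- runif(1, 2, 10)
    if ("position" %in% v) out$mean_position_fraction[i] <- runif(1, 0, 0.1)
    if ("strand" %in% v) out$forward_fraction[i] <- runif(1, 0.95, 1)
    if ("mismatches" %in% v) out$max_mismatches[i] <- sample(5:8, 1L)
    if ("pairing" %in% v) out$pairing_ok[i] <- FALSE
    if ("indel_noise" %in% v) out$frac_additional_indels[i] <- runif(1, 0.6, 0.9)
    unknown <- setdiff(v, c("mapq", "baseq", "position", "strand",
                            "mismatches", "pairing", "blacklist",
                            "indel_noise", "indel_locus"))
    if (length(unknown))
      stop("plan row ", i, ": unknown violation code ",
           paste(unknown, collapse = ", "))
  }
  out
}
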