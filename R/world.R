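#' Configuration of a synthetic ChIP-seq world
#'
#' Bundles every knob of the synthetic-data generator: compendium sizes,
#' the preferential-attachment skew of research attention, the bimodal
#' (expressed / not-expressed) log-normal expression mixture, genome and
#' peak geometry, GWAS SNP count, and the knockout-DEG / TF-marker model
#' with planted "hidden gems". Defaults describe a small but structurally
#' faithful world: 60 TFs across 30 cell lines grouped into 6 classes, 600
#' experiments over 2009-2023 with moderate rich-get-richer skew, a
#' 5-sigma-separated expression mixture, a 2 x 1 Mb genome and 500 SNPs.
#'
#' @param n_tfs,n_cell_types,n_classes,n_experiments Compendium sizes.
#' @param years Inclusive deposit-year range `c(first, last)`.
#' @param attachment_strength Nonnegative preferential-attachment exponent;
#'   0 = uniform attention, larger = stronger rich-get-richer skew.
#' @param pi_expressed Probability a (TF, cell line) pair is truly
#'   expressed.
#' @param mu_low,mu_high,sigma Log-scale means of the not-expressed and
#'   expressed mixture components and their common log-sd (nTPM-like
#'   heavy-tailed values).
#' @param genome Named numeric vector of chromosome lengths (bp).
#' @param n_tss Number of genes with a TSS; the first `n_tfs` genes are the
#'   TFs themselves so that expression, peaks and promoters share one
#'   namespace.
#' @param peak_width,peaks_per_experiment Peak geometry.
#' @param tss_enrichment Fraction of each experiment's peaks placed inside
#'   promoter windows of genes expressed in that experiment's cell type.
#' @param flank Promoter flank (bp) used for enrichment placement.
#' @param n_snps GWAS SNP count.
#' @param deg_meanlog,deg_sdlog Log-normal parameters of knockout DEG
#'   counts.
#' @param marker_delta Positive log-scale shift of DEG counts for marker
#'   TFs.
#' @param marker_fraction Fraction of TFs annotated as cell-type markers.
#' @param gem_deg_threshold DEG count a hidden gem must strictly exceed.
#' @param n_gems Number of planted hidden gems.
#' @param tf_specific_peaks When `TRUE`, each TF's peaks are confined to
#'   its own dedicated genome block, making coverage statistics sensitive
#'   to the diversity of measured TFs.
#' @param seed Integer master seed; every generated artifact is
#'   byte-identical across runs with the same configuration.
#' @return Validated `world_config` list.
#' @export
world_config <- function(n_tfs = 60, n_cell_types = 30, n_classes = 6,
                         n_experiments = 600, years = c(2009, 2023),
                         attachment_strength = 1.5, pi_expressed = 0.3,
                         mu_low = 0, mu_high = 4, sigma = 0.8,
                         genome = c(chr1 = 1e6, chr2 = 1e6),
                         n_tss = n_tfs, peak_width = 200,
                         peaks_per_experiment = 20, tss_enrichment = 0.5,
                         flank = 500, n_snps = 500,
                         deg_meanlog = log(200), deg_sdlog = 1,
                         marker_delta = 1.5, marker_fraction = 0.3,
                         gem_deg_threshold = 1000, n_gems = 2,
                         tf_specific_peaks = FALSE, seed = 1) {
  cfg <- list(n_tfs = n_tfs, n_cell_types = n_cell_types,
              n_classes = n_classes, n_experiments = n_experiments,
              years = years, attachment_strength = attachment_strength,
              pi_expressed = pi_expressed, mu_low = mu_low,
              mu_high = mu_high, sigma = sigma, genome = genome,
              n_tss = n_tss, peak_width = peak_width,
              peaks_per_experiment = peaks_per_experiment,
              tss_enrichment = tss_enrichment, flank = flank,
              n_snps = n_snps, deg_meanlog = deg_meanlog,
              deg_sdlog = deg_sdlog, marker_delta = marker_delta,
              marker_fraction = marker_fraction,
              gem_deg_threshold = gem_deg_threshold, n_gems = n_gems,
              tf_specific_peaks = tf_specific_peaks, seed = as.integer(seed))
  stopifnot(n_tfs >= 1, n_cell_types >= 1, n_classes >= 1,
            n_classes <= n_cell_types, n_experiments >= 1,
            length(years) == 2, years[1] <= years[2],
            attachment_strength >= 0,
            pi_expressed >= 0, pi_expressed <= 1,
            mu_low < mu_high, sigma >= 0,
            length(genome) >= 1, all(genome > peak_width),
            n_tss >= n_tfs, peaks_per_experiment >= 0,
            tss_enrichment >= 0, tss_enrichment <= 1,
            n_snps >= 1, marker_delta > 0,
            marker_fraction >= 0, marker_fraction <= 1, n_gems >= 0)
  class(cfg) <- "world_config"
  cfg
}

# deterministic sub-seed per generator component, kept within 32-bit range
.component_seed <- function(seed, component) {
  (as.numeric(seed) * 131 + sum(utf8ToInt(component))) %% 2147483647
}

.tf_names <- function(cfg) sprintf("TF%03d", seq_len(cfg$n_tfs))
.cell_names <- function(cfg) sprintf("CL%02d", seq_len(cfg$n_cell_types))
.gene_names <- function(cfg) {
  c(.tf_names(cfg),
    if (cfg$n_tss > cfg$n_tfs)
      sprintf("GENE%03d", seq_len(cfg$n_tss - cfg$n_tfs)))
}

#' Balanced cell-type to class partition
#'
#' @param config A [world_config()].
#' @return Data frame `cell_type`, `cell_type_class` assigning the cell
#'   types to `n_classes` contiguous, near-equal classes.
#' @export
generate_class_map <- function(config) {
  cls <- sprintf("Class%02d",
                 rep(seq_len(config$n_classes),
                     length.out = config$n_cell_types,
                     each = ceiling(config$n_cell_types / config$n_classes)))
  data.frame(cell_type = .cell_names(config),
             cell_type_class = cls[seq_len(config$n_cell_types)],
             stringsAsFactors = FALSE)
}

#' Generate experiment metadata with rich-get-richer skew
#'
#' Experiments are assigned sequentially; the probability that the next
#' experiment targets TF `t` (and, independently, cell type `c`) is
#' proportional to `(count + 1)^attachment_strength`, so strength 0 gives
#' uniform attention and larger values reproduce the skewed Lorenz curves
#' and the temporal rich-get-richer correlation seen in real compendia.
#' Deposit dates are uniform over the configured year range.
#'
#' @param config A [world_config()].
#' @return Experiment metadata data frame (`experiment_id`, `antigen`,
#'   `cell_type`, `cell_type_class`, `deposit_date`).
#' @export
generate_metadata <- function(config) {
  set.seed(.component_seed(config$seed, "metadata"))
  tfs <- .tf_names(config)
  cells <- .cell_names(config)
  cmap <- generate_class_map(config)
  alpha <- config$attachment_strength
  tf_counts <- numeric(config$n_tfs)
  cell_counts <- numeric(config$n_cell_types)
  tf_pick <- integer(config$n_experiments)
  cell_pick <- integer(config$n_experiments)
  for (i in seq_len(config$n_experiments)) {
    wt <- (tf_counts + 1)^alpha
    tf_pick[i] <- sample.int(config$n_tfs, 1L, prob = wt / sum(wt))
    tf_counts[tf_pick[i]] <- tf_counts[tf_pick[i]] + 1
    wc <- (cell_counts + 1)^alpha
    cell_pick[i] <- sample.int(config$n_cell_types, 1L, prob = wc / sum(wc))
    cell_counts[cell_pick[i]] <- cell_counts[cell_pick[i]] + 1
  }
  yr <- sample(seq(config$years[1], config$years[2]),
               config$n_experiments, replace = TRUE)
  day <- sample.int(365L, config$n_experiments, replace = TRUE) - 1L
  dates <- as.Date(sprintf("%d-01-01", yr)) + day
  data.frame(experiment_id = sprintf("EXP%05d", seq_len(config$n_experiments)),
             antigen = tfs[tf_pick],
             cell_type = cells[cell_pick],
             cell_type_class = cmap$cell_type_class[cell_pick],
             deposit_date = dates,
             stringsAsFactors = FALSE)
}

#' Generate the bimodal expression matrix and its ground truth
#'
#' Each (TF, cell line) pair is truly expressed with probability
#' `pi_expressed`; its nTPM-like value is drawn from the high or low
#' log-normal component accordingly. The mixture is what the step-function
#' thresholding downstream assumes; at large separation
#' `(mu_high - mu_low) / sigma` the calls recover the truth.
#'
#' @param config A [world_config()].
#' @return List `matrix` (TFs x cell lines) and `true_expressed` (data
#'   frame `tf`, `cell_type`).
#' @export
generate_expression <- function(config) {
  set.seed(.component_seed(config$seed, "expression"))
  tfs <- .tf_names(config)
  cells <- .cell_names(config)
  n <- config$n_tfs * config$n_cell_types
  member <- matrix(stats::rbinom(n, 1L, config$pi_expressed) == 1L,
                   config$n_tfs, config$n_cell_types,
                   dimnames = list(tfs, cells))
  mu <- ifelse(member, config$mu_high, config$mu_low)
  vals <- matrix(stats::rlnorm(n, meanlog = mu, sdlog = config$sigma),
                 config$n_tfs, config$n_cell_types,
                 dimnames = list(tfs, cells))
  idx <- which(member, arr.ind = TRUE)
  true_expressed <- data.frame(tf = tfs[idx[, 1]],
                               cell_type = cells[idx[, 2]],
                               stringsAsFactors = FALSE)
  true_expressed <- true_expressed[order(true_expressed$tf,
                                         true_expressed$cell_type), ]
  rownames(true_expressed) <- NULL
  list(matrix = vals, true_expressed = true_expressed)
}

#' Generate TSS annotations
#'
#' One TSS per gene; the first `n_tfs` genes are the TFs themselves. TSS
#' positions are uniform per chromosome (chromosome chosen proportional to
#' length), kept clear of chromosome edges so promoter windows are never
#' clipped.
#'
#' @param config A [world_config()].
#' @return Data frame `chrom`, `pos` (1-based), `gene`.
#' @export
generate_tss <- function(config) {
  set.seed(.component_seed(config$seed, "tss"))
  genes <- .gene_names(config)
  margin <- config$flank + config$peak_width + 1
  chrom_idx <- sample.int(length(config$genome), config$n_tss,
                          replace = TRUE, prob = config$genome)
  pos <- vapply(chrom_idx, function(ci) {
    sample(seq(margin, config$genome[ci] - margin), 1L)
  }, numeric(1))
  data.frame(chrom = names(config$genome)[chrom_idx],
             pos = as.integer(pos), gene = genes,
             stringsAsFactors = FALSE)
}

#' Generate GWAS SNPs uniformly over the genome
#'
#' @param config A [world_config()].
#' @return SNP table `rsid`, `chrom`, `pos` (1-based), `start`, `end`
#'   (0-based half-open 1-bp intervals).
#' @export
generate_snps <- function(config) {
  set.seed(.component_seed(config$seed, "snps"))
  chrom_idx <- sample.int(length(config$genome), config$n_snps,
                          replace = TRUE, prob = config$genome)
  pos <- vapply(chrom_idx, function(ci) {
    sample.int(config$genome[ci], 1L)
  }, numeric(1))
  data.frame(rsid = sprintf("rs%06d", seq_len(config$n_snps)),
             chrom = names(config$genome)[chrom_idx],
             pos = as.integer(pos),
             start = as.integer(pos) - 1L, end = as.integer(pos),
             stringsAsFactors = FALSE)
}

# contiguous genome block owned by each TF (tf_specific_peaks mode)
.tf_blocks <- function(config) {
  total <- sum(config$genome)
  bounds <- round(seq(0, total, length.out = config$n_tfs + 1))
  offsets <- c(0, cumsum(config$genome))
  blocks <- lapply(seq_len(config$n_tfs), function(t) {
    lo <- bounds[t]; hi <- bounds[t + 1]
    ci <- findInterval(lo, offsets, rightmost.closed = TRUE)
    ci <- min(ci, length(config$genome))
    # clip the block to the chromosome holding its start
    list(chrom = names(config$genome)[ci],
         start = lo - offsets[ci],
         end = min(hi - offsets[ci], config$genome[ci]))
  })
  names(blocks) <- .tf_names(config)
  blocks
}

#' Generate per-experiment peak files
#'
#' For each experiment, a fraction `tss_enrichment` of its peaks is placed
#' inside promoter windows (TSS +/- `flank`) of genes truly expressed in
#' the experiment's cell type; the remainder falls uniformly on the genome.
#' With `tf_specific_peaks = TRUE` every peak of an experiment instead
#' falls inside the targeted TF's dedicated genome block, so coverage
#' accrues with TF diversity rather than with raw experiment count.
#'
#' @param config A [world_config()].
#' @param metadata Experiment metadata from [generate_metadata()].
#' @param tss TSS table from [generate_tss()].
#' @param true_expressed Ground-truth expressed pairs.
#' @return Named list (experiment ID) of peak data frames (`chrom`,
#'   `start`, `end`, `name`; 0-based half-open).
#' @export
generate_peaks <- function(config, metadata, tss, true_expressed) {
  set.seed(.component_seed(config$seed, "peaks"))
  w <- config$peak_width
  k <- config$peaks_per_experiment
  genome <- config$genome
  blocks <- if (config$tf_specific_peaks) .tf_blocks(config)
  uniform_peak <- function(n) {
    ci <- sample.int(length(genome), n, replace = TRUE, prob = genome)
    st <- vapply(ci, function(c_) sample.int(genome[c_] - w, 1L) - 1L,
                 numeric(1))
    data.frame(chrom = names(genome)[ci], start = as.integer(st),
               end = as.integer(st + w), stringsAsFactors = FALSE)
  }
  out <- vector("list", nrow(metadata))
  names(out) <- metadata$experiment_id
  for (i in seq_len(nrow(metadata))) {
    if (k == 0L) {
      out[[i]] <- data.frame(chrom = character(), start = integer(),
                             end = integer(), name = character(),
                             stringsAsFactors = FALSE)
      next
    }
    if (config$tf_specific_peaks) {
      b <- blocks[[metadata$antigen[i]]]
      span <- b$end - b$start - w
      st <- b$start + sample.int(max(span, 1L), k, replace = TRUE) - 1L
      st <- pmin(st, genome[[b$chrom]] - w)
      peaks <- data.frame(chrom = b$chrom, start = as.integer(st),
                          end = as.integer(st + w),
                          stringsAsFactors = FALSE)
    } else {
      genes_c <- true_expressed$tf[true_expressed$cell_type ==
                                     metadata$cell_type[i]]
      tss_c <- tss[tss$gene %in% genes_c, , drop = FALSE]
      n_enr <- if (nrow(tss_c) > 0L) round(k * config$tss_enrichment) else 0L
      enr <- NULL
      if (n_enr > 0L) {
        gi <- sample.int(nrow(tss_c), n_enr, replace = TRUE)
        win_start <- pmax(0L, tss_c$pos[gi] - 1L - config$flank)
        win_len <- 2L * config$flank + 1L
        st <- win_start + vapply(seq_len(n_enr), function(j) {
          sample.int(win_len - w + 1L, 1L) - 1L
        }, numeric(1))
        enr <- data.frame(chrom = tss_c$chrom[gi], start = as.integer(st),
                          end = as.integer(st + w),
                          stringsAsFactors = FALSE)
      }
      peaks <- rbind(enr, if (k - n_enr > 0L) uniform_peak(k - n_enr))
    }
    peaks$name <- sprintf("%s_peak%03d", metadata$experiment_id[i],
                          seq_len(nrow(peaks)))
    rownames(peaks) <- NULL
    out[[i]] <- peaks
  }
  out
}

#' Generate knockout DEG counts, TF markers, and planted hidden gems
#'
#' DEG counts per (TF, class) knockout experiment are log-normal; marker
#' TFs are shifted up by `marker_delta` on the log scale. `n_gems`
#' expressed-but-unmeasured (TF, class) pairs are planted as hidden gems:
#' their TF is flagged as a marker and their DEG count strictly exceeds
#' `gem_deg_threshold`. Every other unmeasured pair whose TF is a marker is
#' clamped to the threshold or below, so the planted gems are exactly the
#' pairs satisfying the gem predicates — giving the downstream filter a
#' known answer.
#'
#' @param config A [world_config()].
#' @param metadata Experiment metadata.
#' @param true_expressed Ground-truth expressed (TF, cell line) pairs.
#' @param class_map Cell-type to class mapping.
#' @return List `deg` (data frame `tf`, `sample`, `n_deg`, `is_marker`),
#'   `markers` (character vector), `planted_gems` (data frame `tf`,
#'   `cell_type_class`).
#' @export
generate_deg_and_markers <- function(config, metadata, true_expressed,
                                     class_map) {
  set.seed(.component_seed(config$seed, "deg"))
  tfs <- .tf_names(config)
  classes <- unique(class_map$cell_type_class)
  markers <- sort(sample(tfs, round(config$marker_fraction * config$n_tfs)))

  # truth-level expressed and measured pair sets at class level
  expr_class <- unique(data.frame(
    tf = true_expressed$tf,
    cls = class_map$cell_type_class[match(true_expressed$cell_type,
                                          class_map$cell_type)],
    stringsAsFactors = FALSE))
  meas_class <- unique(data.frame(
    tf = metadata$antigen,
    cls = class_map$cell_type_class[match(metadata$cell_type,
                                          class_map$cell_type)],
    stringsAsFactors = FALSE))
  key <- function(d) paste(d$tf, d$cls, sep = "\r")
  unmeasured <- expr_class[!(key(expr_class) %in% key(meas_class)), ,
                           drop = FALSE]
  if (config$n_gems > nrow(unmeasured))
    stop("infeasible gem planting: only ", nrow(unmeasured),
         " expressed-but-unmeasured (TF, class) pairs exist")
  gem_idx <- if (config$n_gems > 0L)
    sort(sample.int(nrow(unmeasured), config$n_gems)) else integer(0)
  gems <- unmeasured[gem_idx, , drop = FALSE]
  markers <- sort(unique(c(markers, gems$tf)))

  # baseline knockout records: each TF assayed in 1-3 random classes
  rows <- lapply(seq_along(tfs), function(t) {
    n_cls <- sample.int(3L, 1L)
    cls <- sample(classes, min(n_cls, length(classes)))
    mu <- config$deg_meanlog +
      if (tfs[t] %in% markers) config$marker_delta else 0
    data.frame(tf = tfs[t], sample = cls,
               n_deg = as.integer(round(stats::rlnorm(length(cls), mu,
                                                      config$deg_sdlog))),
               stringsAsFactors = FALSE)
  })
  deg <- do.call(rbind, rows)

  # plant the gems: DEG strictly above the threshold
  if (nrow(gems) > 0L) {
    gem_rows <- data.frame(
      tf = gems$tf, sample = gems$cls,
      n_deg = as.integer(config$gem_deg_threshold +
                           ceiling(stats::rlnorm(nrow(gems), log(500), 0.5))),
      stringsAsFactors = FALSE)
    # drop any pre-existing rows for the planted pairs, then append
    deg <- deg[!(paste(deg$tf, deg$sample, sep = "\r") %in%
                   paste(gem_rows$tf, gem_rows$sample, sep = "\r")), ,
               drop = FALSE]
    deg <- rbind(deg, gem_rows)
  }

  # exclusivity: no other unmeasured marker pair may cross the threshold
  deg_key <- paste(deg$tf, deg$sample, sep = "\r")
  gem_key <- paste(gems$tf, gems$cls, sep = "\r")
  clamp <- deg$tf %in% markers &
    !(deg_key %in% key(meas_class)) &
    !(deg_key %in% gem_key)
  deg$n_deg[clamp] <- pmin(deg$n_deg[clamp],
                           as.integer(config$gem_deg_threshold))
  deg$is_marker <- deg$tf %in% markers
  deg <- deg[order(deg$tf, deg$sample), , drop = FALSE]
  rownames(deg) <- NULL
  planted <- data.frame(tf = gems$tf, cell_type_class = gems$cls,
                        stringsAsFactors = FALSE)
  list(deg = deg, markers = markers, planted_gems = planted)
}

#' Generate per-TF publication counts
#'
#' Publications are a noisy increasing function of a TF's experiment count,
#' emulating the attention signal that tracks data accrual.
#'
#' @param config A [world_config()].
#' @param metadata Experiment metadata.
#' @return Named integer vector of publication counts per TF.
#' @export
generate_publications <- function(config, metadata) {
  set.seed(.component_seed(config$seed, "publications"))
  counts <- table(factor(metadata$antigen, levels = .tf_names(config)))
  pubs <- stats::rpois(config$n_tfs, lambda = 2 + 3 * as.numeric(counts))
  names(pubs) <- .tf_names(config)
  pubs
}

#' Generate a complete synthetic world
#'
#' Runs every generator component under seeds derived from the master seed
#' and assembles the world plus its ground truth.
#'
#' @param config A [world_config()].
#' @return List with `config`, `metadata`, `expression` (matrix), `tss`,
#'   `snps`, `peaks` (named list), `deg`, `markers`, `publications`,
#'   `class_map`, and `ground_truth` (list `true_expressed`,
#'   `planted_gems`).
#' @export
generate_world <- function(config = world_config()) {
  metadata <- generate_metadata(config)
  expr <- generate_expression(config)
  tss <- generate_tss(config)
  snps <- generate_snps(config)
  peaks <- generate_peaks(config, metadata, tss, expr$true_expressed)
  class_map <- generate_class_map(config)
  dm <- generate_deg_and_markers(config, metadata, expr$true_expressed,
                                 class_map)
  pubs <- generate_publications(config, metadata)
  list(config = config, metadata = metadata, expression = expr$matrix,
       tss = tss, snps = snps, peaks = peaks, deg = dm$deg,
       markers = dm$markers, publications = pubs, class_map = class_map,
       ground_truth = list(true_expressed = expr$true_expressed,
                           planted_gems = dm$planted_gems))
}

#' Write a synthetic world to disk in the pipeline's input formats
#'
#' Emits the same file dialects the readers in this package consume: TSVs
#' for metadata/expression/SNPs/DEG/markers/class map, BED per experiment,
#' and a YAML manifest recording the seed and file paths.
#'
#' @param world A world from [generate_world()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  peaks_dir <- file.path(dir, "peaks")
  dir.create(peaks_dir, showWarnings = FALSE)
  write_experiment_table(world$metadata, file.path(dir, "metadata.tsv"))
  write_expression_matrix(world$expression, file.path(dir, "expression.tsv"))
  utils::write.table(world$tss, file.path(dir, "tss.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(world$snps[, c("rsid", "chrom", "pos")],
                     file.path(dir, "snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(world$deg, file.path(dir, "deg.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(tf = world$markers),
                     file.path(dir, "markers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(world$class_map, file.path(dir, "class_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(tf = names(world$publications),
                                publications = as.integer(world$publications)),
                     file.path(dir, "publications.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (id in names(world$peaks))
    write_bed(world$peaks[[id]], file.path(peaks_dir, paste0(id, ".bed")))
  utils::write.table(world$ground_truth$true_expressed,
                     file.path(dir, "truth_expressed.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(world$ground_truth$planted_gems,
                     file.path(dir, "truth_gems.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(seed = world$config$seed,
                   files = list(metadata = "metadata.tsv",
                                expression = "expression.tsv",
                                tss = "tss.tsv", snps = "snps.tsv",
                                deg = "deg.tsv", markers = "markers.tsv",
                                class_map = "class_map.tsv",
                                publications = "publications.tsv",
                                peaks_dir = "peaks",
                                truth_expressed = "truth_expressed.tsv",
                                truth_gems = "truth_gems.tsv"))
  path <- file.path(dir, "world.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read a written synthetic world back from disk
#'
#' Counterpart of [write_world()]: loads every table through the package's
#' validating readers, including the ground-truth files when present.
#'
#' @param dir Directory containing `world.yaml`.
#' @return World list in the same shape as [generate_world()] (without the
#'   original `config`; the manifest seed is attached as `seed`).
#' @export
read_world <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "world.yaml"))
  fp <- function(key) file.path(dir, manifest$files[[key]])
  peak_files <- list.files(fp("peaks_dir"), pattern = "\\.bed$",
                           full.names = TRUE)
  peaks <- lapply(peak_files, read_bed)
  names(peaks) <- sub("\\.bed$", "", basename(peak_files))
  pubs <- utils::read.delim(fp("publications"), stringsAsFactors = FALSE)
  truth <- NULL
  if (file.exists(fp("truth_expressed")))
    truth <- list(
      true_expressed = utils::read.delim(fp("truth_expressed"),
                                         stringsAsFactors = FALSE),
      planted_gems = utils::read.delim(fp("truth_gems"),
                                       stringsAsFactors = FALSE))
  list(metadata = read_experiment_table(fp("metadata")),
       expression = read_expression_matrix(fp("expression")),
       tss = utils::read.delim(fp("tss"), stringsAsFactors = FALSE),
       snps = read_snp_table(fp("snps")),
       deg = read_deg_table(fp("deg")),
       markers = read_marker_table(fp("markers")),
       class_map = read_class_map(fp("class_map")),
       publications = stats::setNames(pubs$publications, pubs$tf),
       peaks = peaks, ground_truth = truth, seed = manifest$seed)
}
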