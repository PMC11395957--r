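#' Simulation configuration
#'
#' Bundles every knob of the genotype/phenotype simulator. Defaults emulate
#' a farmed sturgeon breeding population: 673 individuals, dense biallelic
#' SNPs with MAF >= 0.05, and LD that decays with physical distance to
#' r^2 = 0.05 at 20 kb. The decay model is r^2(d) = r2_adjacent *
#' exp(-d / ld_scale_bp); the default pair (0.25, 20000/log(5)) puts the
#' 0.05 crossing at exactly 20 kb.
#'
#' @param n_samples number of diploid individuals.
#' @param n_markers total marker count across all chromosomes.
#' @param chrom_lengths numeric vector of chromosome lengths in bp; markers
#'   are allocated proportionally to length.
#' @param r2_adjacent short-range plateau of genotype r^2 (at distance 0).
#' @param ld_scale_bp exponential decay length-scale of r^2, in bp.
#' @param maf_range two-element vector of minor-allele-frequency bounds the
#'   simulated allele frequencies are drawn from.
#' @param n_qtl number of causal markers for the additive trait.
#' @param h2_target narrow-sense heritability, realised exactly in-sample.
#' @param trait_type `"continuous"` or `"ordinal"`.
#' @param ordinal_probs category probabilities for ordinal traits (codes
#'   `1..length(ordinal_probs)`); default four balanced categories.
#' @param n_families number of full-sib families (0 = unrelated panmixia).
#' @param seed root seed; all stages derive named substreams from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 673, n_markers = 5000,
                       chrom_lengths = rep(5e6, 10),
                       r2_adjacent = 0.25, ld_scale_bp = 20000 / log(5),
                       maf_range = c(0.05, 0.5),
                       n_qtl = 50, h2_target = 0.6,
                       trait_type = c("continuous", "ordinal"),
                       ordinal_probs = rep(0.25, 4),
                       n_families = 0, seed = 1) {
  trait_type <- match.arg(trait_type)
  stopifnot(n_samples > 0, n_markers > 0, all(chrom_lengths > 0),
            h2_target >= 0, h2_target <= 1, n_qtl <= n_markers,
            r2_adjacent >= 0, r2_adjacent < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
            abs(sum(ordinal_probs) - 1) < 1e-8)
  structure(list(n_samples = as.integer(n_samples),
                 n_markers = as.integer(n_markers),
                 chrom_lengths = chrom_lengths,
                 r2_adjacent = r2_adjacent, ld_scale_bp = ld_scale_bp,
                 maf_range = maf_range, n_qtl = as.integer(n_qtl),
                 h2_target = h2_target, trait_type = trait_type,
                 ordinal_probs = ordinal_probs,
                 n_families = as.integer(n_families),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# correlation between two thresholded-Gaussian indicators 1{Z < qnorm(p)}
# with latent correlation rho; exact via 1-D quadrature of the bivariate
# normal orthant probability.
.binary_corr <- function(rho, p1, p2) {
  if (rho >= 1) return(1)
  if (rho <= 0) return(0)
  q1 <- stats::qnorm(p1); q2 <- stats::qnorm(p2)
  f <- function(z) stats::dnorm(z) * stats::pnorm((q2 - rho * z) / sqrt(1 - rho^2))
  p11 <- stats::integrate(f, -8, q1, rel.tol = 1e-9)$value
  (p11 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

# memoised inverse calibration: latent rho needed to hit a target genotype
# correlation for a pair of allele frequencies (bucketed to a 0.05 grid so
# the quadrature tables are shared across markers and calls)
.calib_cache <- new.env(parent = emptyenv())

.latent_calibration <- function(p1, p2) {
  b <- function(p) min(0.95, max(0.05, round(p / 0.05) * 0.05))
  pl <- min(b(p1), b(p2)); ph <- max(b(p1), b(p2))
  key <- sprintf("%.2f_%.2f", pl, ph)
  fn <- .calib_cache[[key]]
  if (is.null(fn)) {
    rho_grid <- seq(0, 0.999, length.out = 40)
    r_grid <- vapply(rho_grid, .binary_corr, numeric(1), p1 = pl, p2 = ph)
    r_grid[1] <- 0
    # targets beyond the attainable (Frechet-type) bound clamp to max rho
    fn <- stats::approxfun(cummax(r_grid), rho_grid, rule = 2, ties = "ordered")
    .calib_cache[[key]] <- fn
  }
  fn
}

#' Simulate genotypes with distance-decaying linkage disequilibrium
#'
#' Haplotypes are drawn from a latent Gaussian process along each
#' chromosome: adjacent markers at distance d receive a latent correlation
#' calibrated so that the resulting *genotype* correlation matches the
#' target decay curve r^2(d) = r2_adjacent * exp(-d / ld_scale_bp). The
#' latent series is thresholded at each marker's allele-frequency quantile
#' to give a haplotype allele; two independent haplotypes are summed per
#' individual. With `n_families > 0`, founder haplotypes are simulated the
#' same way and offspring haplotypes are produced by recombining each
#' parent's pair (about one crossover per chromosome), creating full-sib
#' block structure. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return A `GenotypeMatrix` with markers sorted by (chromosome, position).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "genotypes"))
  n <- config$n_samples
  n_chr <- length(config$chrom_lengths)
  m_per <- pmax(1L, round(config$n_markers * config$chrom_lengths / sum(config$chrom_lengths)))
  # fix rounding so totals match
  while (sum(m_per) != config$n_markers) {
    i <- if (sum(m_per) > config$n_markers) which.max(m_per) else which.min(m_per)
    m_per[i] <- m_per[i] + sign(config$n_markers - sum(m_per))
  }
  maf <- stats::runif(config$n_markers, config$maf_range[1], config$maf_range[2])
  flip <- stats::runif(config$n_markers) < 0.5
  p_alt <- ifelse(flip, maf, 1 - maf)

  chrom <- rep(paste0("chr", seq_len(n_chr)), m_per)
  pos <- unlist(lapply(seq_len(n_chr), function(c) {
    sort(sample.int(config$chrom_lengths[c], m_per[c]))
  }))
  n_hap <- if (config$n_families > 0) NULL else 2L * n

  draw_hap_block <- function(n_h) {
    # latent AR chain per chromosome, vectorised over haplotypes
    H <- matrix(0L, n_h, config$n_markers)
    off <- 0L
    for (c in seq_len(n_chr)) {
      m <- m_per[c]
      idx <- off + seq_len(m)
      d <- diff(pos[idx])
      r_target <- sqrt(config$r2_adjacent * exp(-d / config$ld_scale_bp))
      # calibrate on the minor-allele scale (higher attainable correlation)
      # and carry the coding sign into the latent chain; r^2 is unaffected
      pm <- pmin(p_alt[idx], 1 - p_alt[idx])
      sgn <- ifelse(p_alt[idx] <= 0.5, 1, -1)
      rho <- vapply(seq_along(d), function(j) {
        sgn[j] * sgn[j + 1] *
          .latent_calibration(pm[j], pm[j + 1])(r_target[j])
      }, numeric(1))
      z <- matrix(0, n_h, m)
      z[, 1] <- stats::rnorm(n_h)
      if (m > 1) for (j in seq_len(m - 1)) {
        z[, j + 1] <- rho[j] * z[, j] + sqrt(1 - rho[j]^2) * stats::rnorm(n_h)
      }
      H[, idx] <- (z < matrix(stats::qnorm(p_alt[idx]), n_h, m, byrow = TRUE)) + 0L
      off <- off + m
    }
    H
  }

  if (config$n_families == 0) {
    H <- draw_hap_block(2L * n)
    dos <- H[seq_len(n) * 2L - 1L, , drop = FALSE] + H[seq_len(n) * 2L, , drop = FALSE]
  } else {
    fam_sizes <- rep(n %/% config$n_families, config$n_families)
    extra <- n - sum(fam_sizes)
    if (extra > 0) fam_sizes[seq_len(extra)] <- fam_sizes[seq_len(extra)] + 1L
    founders <- draw_hap_block(4L * config$n_families)  # 2 parents x 2 haps
    recombine <- function(h1, h2) {
      out <- integer(config$n_markers)
      off <- 0L
      for (c in seq_len(n_chr)) {
        m <- m_per[c]; idx <- off + seq_len(m)
        n_x <- stats::rpois(1, 1)
        cuts <- sort(stats::runif(n_x, 0, config$chrom_lengths[c]))
        seg <- findInterval(pos[idx], cuts)
        use1 <- (seg + stats::rbinom(1, 1, 0.5)) %% 2 == 0
        out[idx] <- ifelse(use1, h1[idx], h2[idx])
        off <- off + m
      }
      out
    }
    dos <- matrix(0L, n, config$n_markers)
    row <- 1L
    fam <- integer(n)
    for (f in seq_len(config$n_families)) {
      par <- founders[(f - 1L) * 4L + 1:4, , drop = FALSE]
      for (k in seq_len(fam_sizes[f])) {
        dos[row, ] <- recombine(par[1, ], par[2, ]) + recombine(par[3, ], par[4, ])
        fam[row] <- f
        row <- row + 1L
      }
    }
  }
  rownames(dos) <- sprintf("S%04d", seq_len(n))
  map <- data.frame(id = sprintf("SNP%06d", seq_len(config$n_markers)),
                    chrom = chrom, pos = as.integer(pos),
                    ref = "A", alt = "G", stringsAsFactors = FALSE)
  gm <- genotype_matrix(dos, map)
  if (config$n_families > 0) attr(gm, "family") <- fam
  gm
}

#' Simulate additive phenotypes with known QTLs
#'
#' QTL markers are sampled without replacement; allelic effects are standard
#' normal. Genetic values and residuals are rescaled so that the in-sample
#' variance ratio var(g) / (var(g) + var(e)) equals `h2_target` exactly,
#' which gives parameter-recovery tests an exact target. Ordinal traits cut
#' the continuous liability at the quantile thresholds implied by
#' `ordinal_probs` into integer codes `1..K`.
#'
#' @param gm a `GenotypeMatrix` (typically from [simulate_genotypes()]).
#' @param config a [sim_config()]; fields `n_qtl`, `h2_target`,
#'   `trait_type`, `ordinal_probs` and `seed` are used.
#' @param trait_name column name for the trait (default `"trait"`).
#' @return list with `phenotypes` (data.frame sample_id + trait) and
#'   `truth` (list: qtl ids, scaled effects, genetic values, realised h2,
#'   liability for ordinal traits).
#' @export
simulate_phenotypes <- function(gm, config, trait_name = "trait") {
  stopifnot(inherits(gm, "GenotypeMatrix"), inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, paste0("phenotypes:", trait_name)))
  n <- nrow(gm$dosages)
  qtl_idx <- sort(sample.int(ncol(gm$dosages), config$n_qtl))
  beta <- stats::rnorm(config$n_qtl)
  g_raw <- as.vector(gm$dosages[, qtl_idx, drop = FALSE] %*% beta)
  g_raw <- g_raw - mean(g_raw)
  h2 <- config$h2_target
  if (stats::var(g_raw) == 0 && h2 > 0)
    stop("all sampled QTLs are monomorphic; cannot realise h2 > 0")
  e <- stats::rnorm(n)
  e <- e - mean(e)
  # residualise e on g in-sample so the variance ratio is exact by construction
  if (h2 > 0 && stats::var(g_raw) > 0)
    e <- e - g_raw * sum(e * g_raw) / sum(g_raw^2)
  e <- e / stats::sd(e)
  g <- if (h2 > 0) g_raw / stats::sd(g_raw) * sqrt(h2) else g_raw * 0
  y <- g + e * sqrt(1 - h2)
  scale_fac <- if (h2 > 0) sqrt(h2) / stats::sd(g_raw) else 0
  liability <- y
  if (config$trait_type == "ordinal") {
    cuts <- stats::quantile(liability, cumsum(config$ordinal_probs)[-length(config$ordinal_probs)])
    y <- findInterval(liability, cuts, left.open = TRUE) + 1L
  }
  list(
    phenotypes = stats::setNames(
      data.frame(sample_id = rownames(gm$dosages), y, stringsAsFactors = FALSE),
      c("sample_id", trait_name)),
    truth = list(qtl_ids = gm$map$id[qtl_idx],
                 qtl_effects = beta * scale_fac,
                 qtl_effects_raw = beta,
                 genetic_values = g,
                 realized_h2 = if (stats::var(y) > 0 && config$trait_type == "continuous")
                   stats::var(g) / (stats::var(g) + stats::var(e * sqrt(1 - h2))) else h2,
                 liability = liability)
  )
}

#' Write a self-contained simulated fixture to disk
#'
#' Emits a plain-text VCF, a phenotype TSV, a toy GFF3 gene annotation with
#' genes both inside and outside +-20 kb of planted QTLs, and a JSON truth
#' file. Preset `"sturgeon"` emulates the target study design: 673
#' individuals in 26 full-sib families, 5,000 markers, three traits (two
#' continuous with h2 0.50 / 0.63 and an ordinal 1-4 colour score with h2
#' 0.61 and mean near 2.45). Preset `"mini"` is a fast small fixture for
#' tests and examples.
#'
#' @param preset `"sturgeon"` or `"mini"`.
#' @param out_dir output directory (created if absent).
#' @param seed root seed (default 1).
#' @return invisible list of written paths.
#' @export
make_fixture <- function(preset = c("sturgeon", "mini"), out_dir, seed = 1) {
  preset <- match.arg(preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (preset == "sturgeon") {
    base <- sim_config(n_samples = 673, n_markers = 5000,
                       chrom_lengths = rep(5e6, 10), n_families = 26, seed = seed)
    traits <- list(
      caviar_yield = list(h2 = 0.50, type = "continuous", n_qtl = 50,
                          mean = 0.190, sd = 0.057),
      caviar_color = list(h2 = 0.61, type = "ordinal", n_qtl = 50,
                          probs = c(0.10, 0.45, 0.35, 0.10)),
      body_weight = list(h2 = 0.63, type = "continuous", n_qtl = 50,
                         mean = 19.933, sd = 4.029))
  } else {
    base <- sim_config(n_samples = 120, n_markers = 400,
                       chrom_lengths = rep(2e6, 2), n_qtl = 10, seed = seed)
    traits <- list(
      trait_cont = list(h2 = 0.6, type = "continuous", n_qtl = 10,
                        mean = 10, sd = 2),
      trait_ord = list(h2 = 0.6, type = "ordinal", n_qtl = 10,
                       probs = rep(0.25, 4)))
  }
  gm <- simulate_genotypes(base)
  pheno <- data.frame(sample_id = rownames(gm$dosages), stringsAsFactors = FALSE)
  truth <- list()
  for (tn in names(traits)) {
    tc <- traits[[tn]]
    cfg <- base
    cfg$h2_target <- tc$h2; cfg$trait_type <- tc$type; cfg$n_qtl <- tc$n_qtl
    if (!is.null(tc$probs)) cfg$ordinal_probs <- tc$probs
    sim <- simulate_phenotypes(gm, cfg, trait_name = tn)
    yv <- sim$phenotypes[[tn]]
    # continuous traits get a realistic location/scale (h2 is unaffected)
    if (tc$type == "continuous" && !is.null(tc$mean))
      yv <- round(tc$mean + tc$sd * yv, 4)
    pheno[[tn]] <- yv
    truth[[tn]] <- sim$truth[c("qtl_ids", "qtl_effects", "realized_h2")]
  }
  vcf_path <- file.path(out_dir, "genotypes.vcf")
  write_genotypes(gm, vcf_path, "vcf")
  ph_path <- file.path(out_dir, "phenotypes.tsv")
  write_phenotypes(pheno, ph_path)
  gff_path <- file.path(out_dir, "genes.gff3")
  # anchor near-genes at each trait's largest-effect QTLs so significant
  # scan regions have annotated neighbours
  top_qtl <- unique(unlist(lapply(truth, function(tt)
    tt$qtl_ids[order(-abs(tt$qtl_effects))][seq_len(min(4, length(tt$qtl_ids)))])))
  .write_toy_gff(gm, top_qtl, gff_path, seed = substream_seed(seed, "gff"))
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(list(vcf = vcf_path, phenotypes = ph_path, gff = gff_path,
                 truth = truth_path))
}

# toy annotation: one gene near (within 20 kb of) each of the first planted
# QTLs, plus decoy genes guaranteed > 50 kb from every QTL
.write_toy_gff <- function(gm, qtl_ids, path, seed = 1) {
  set.seed(seed)
  qtl <- gm$map[gm$map$id %in% qtl_ids, , drop = FALSE]
  lines <- c("##gff-version 3")
  gid <- 0L
  mk <- function(chrom, start, end, name) {
    sprintf("%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=gene%04d;Name=%s",
            chrom, as.integer(max(1, start)), as.integer(end),
            sample(c("+", "-"), 1), gid, name)
  }
  for (i in seq_len(min(10, nrow(qtl)))) {
    gid <- gid + 1L
    s <- qtl$pos[i] + sample(-15000:10000, 1)
    lines <- c(lines, mk(qtl$chrom[i], s, s + 5000, sprintf("NEARQTL%02d", i)))
  }
  chroms <- unique(gm$map$chrom)
  for (i in seq_len(10)) {
    ch <- sample(chroms, 1)
    cand <- 0
    for (try in 1:50) {
      s <- sample.int(max(gm$map$pos[gm$map$chrom == ch]), 1)
      dmin <- suppressWarnings(min(abs(qtl$pos[qtl$chrom == ch] - s)))
      if (!is.finite(dmin) || dmin > 50000) { cand <- s; break }
    }
    if (cand > 0) {
      gid <- gid + 1L
      lines <- c(lines, mk(ch, cand, cand + 4000, sprintf("DECOY%02d", i)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
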