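#' Synthetic data generators for every pipeline stage
#'
#' Seeded generators producing (i) blinking-emitter image stacks with
#' ground truth, (ii) two-channel nuclear point clouds with planted ALU
#' clusters and an annular heterochromatin environment, (iii) genomes with
#' planted, optionally mutated repeat copies, and (iv) quadratic
#' dose-response count series. Each generator is bit-reproducible for a
#' fixed seed and emits the same formats the analysis modules consume.
#'
#' @name synthgen
NULL

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Blinking-emitter model
#'
#' Bernoulli blinking: in every frame each emitter is ON independently with
#' `blink_prob`; an ON emitter deposits photons through a discretized
#' isotropic Gaussian PSF onto a Poisson background, and pixel counts are
#' Poisson around their expectations.
#'
#' @param positions two-column matrix of true emitter positions in nm.
#' @param mean_photons expected photons per blink (default 1000).
#' @param blink_prob per-frame ON probability in (0, 1] (default 0.02).
#' @param background_mean mean background in counts/pixel (default 10).
#' @param psf_sigma_nm PSF standard deviation in nm (default 100).
#' @param frames number of frames (default 2000, one acquisition channel).
#' @param seed RNG seed (default NULL: use the current RNG state).
#' @return an `emitter_model` list.
#' @export
emitter_model <- function(positions, mean_photons = 1000, blink_prob = 0.02,
                          background_mean = 10, psf_sigma_nm = 100,
                          frames = 2000L, seed = NULL) {
  cl_assert(is.matrix(positions) && ncol(positions) == 2L && nrow(positions) > 0,
            "positions must be a two-column matrix")
  cl_assert(mean_photons > 0 && background_mean >= 0 && psf_sigma_nm > 0,
            "rates and widths must be positive")
  cl_assert(blink_prob > 0 && blink_prob <= 1, "blink_prob must be in (0, 1]")
  cl_assert(frames >= 1, "frames must be >= 1")
  structure(list(positions = positions, mean_photons = mean_photons,
                 blink_prob = blink_prob, background_mean = background_mean,
                 psf_sigma_nm = psf_sigma_nm, frames = as.integer(frames),
                 seed = seed),
            class = "emitter_model")
}

#' Generate a blinking-emitter image stack with ground truth
#'
#' @param model an [emitter_model()].
#' @param frame_shape integer `(rows, cols)` of each frame (default
#'   `c(64, 64)`).
#' @param pixel_size_nm camera pixel pitch in nm (default 100).
#' @return list with `frames` (list of integer count matrices) and `truth`
#'   (tibble `frame`, `emitter`, `x_nm`, `y_nm`, `photons` listing every ON
#'   event; `photons` is the expected photon sum of the event).
#' @export
generate_stack <- function(model, frame_shape = c(64L, 64L),
                           pixel_size_nm = 100) {
  nr <- frame_shape[1L]; nc <- frame_shape[2L]
  pos <- model$positions
  cl_assert(all(pos[, 1L] > 0 & pos[, 1L] < nc * pixel_size_nm &
                  pos[, 2L] > 0 & pos[, 2L] < nr * pixel_size_nm),
            "all emitters must lie inside the field of view")
  with_seed(model$seed, {
    xe <- (0:nc) * pixel_size_nm
    ye <- (0:nr) * pixel_size_nm
    # per-emitter PSF pixel-mass matrices (truncation beyond the frame only)
    kern <- lapply(seq_len(nrow(pos)), function(i) {
      px <- diff(stats::pnorm(xe, pos[i, 1L], model$psf_sigma_nm))
      py <- diff(stats::pnorm(ye, pos[i, 2L], model$psf_sigma_nm))
      py %o% px
    })
    frames <- vector("list", model$frames)
    truth <- vector("list", model$frames)
    for (f in seq_len(model$frames)) {
      lam <- matrix(model$background_mean, nr, nc)
      on <- which(stats::runif(nrow(pos)) < model$blink_prob)
      for (i in on) lam <- lam + model$mean_photons * kern[[i]]
      frames[[f]] <- matrix(stats::rpois(nr * nc, lam), nr, nc)
      if (length(on)) {
        truth[[f]] <- tibble::tibble(frame = f, emitter = on,
                                     x_nm = pos[on, 1L], y_nm = pos[on, 2L],
                                     photons = model$mean_photons)
      }
    }
    truth <- truth[!vapply(truth, is.null, logical(1))]
    list(frames = frames,
         truth = if (length(truth)) do.call(rbind, truth) else
           tibble::tibble(frame = integer(), emitter = integer(),
                          x_nm = numeric(), y_nm = numeric(),
                          photons = numeric()))
  })
}

#' Nuclear point-cloud model
#'
#' Defines a two-channel synthetic nucleus. The ALU channel is a
#' Neyman-Scott-type clustered process: `n_clusters` parent centres placed
#' uniformly in the nucleus disc (with a hard-core minimum separation so
#' planted clusters stay well separated), each scattering
#' `points_per_cluster_min + Poisson(mean - min)` Gaussian offspring of
#' width `cluster_sigma_nm`, plus a uniform noise fraction. Localization
#' error adds isotropic Gaussian jitter of `loc_precision_nm` (about 10 nm,
#' the typical localization precision). The heterochromatin channel is an
#' inhomogeneous Poisson process: uniform background of
#' `het_background_per_nm2` over the nucleus, suppressed to zero within
#' `het_inner_nm` of every cluster centre and elevated by the factor
#' `het_ratio` in the annulus `[het_inner_nm, het_outer_nm)` — ALU and
#' heterochromatin associate spatially but do not co-localize.
#'
#' @param n_clusters planted ALU clusters per nucleus (default 200).
#' @param nucleus_radius_nm nucleus radius (default 7000, a ~14-um
#'   nucleus). Parents keep `het_outer_nm` clear of the edge.
#' @param min_separation_nm hard-core distance between parent centres
#'   (default 500).
#' @param points_per_cluster_min minimum localizations per cluster
#'   (default 10).
#' @param points_per_cluster_mean mean localizations per cluster
#'   (default 20).
#' @param cluster_sigma_nm Gaussian scatter of cluster members (default 40).
#' @param alu_noise_fraction fraction of ALU-channel points that are
#'   uniform noise (default 0.05).
#' @param loc_precision_nm localization jitter sigma in nm (default 10).
#' @param het_inner_nm,het_outer_nm heterochromatin annulus radii
#'   (defaults 100 and 300).
#' @param het_ratio annulus intensity ratio over background (default 3; 1
#'   disables elevation, values below 1 model de-compaction).
#' @param het_background_per_nm2 background heterochromatin intensity in
#'   points/nm^2 (default 2e-4).
#' @param seed RNG seed.
#' @return a `nucleus_model` list.
#' @export
nucleus_model <- function(n_clusters = 200L, nucleus_radius_nm = 7000,
                          min_separation_nm = 500,
                          points_per_cluster_min = 10L,
                          points_per_cluster_mean = 20,
                          cluster_sigma_nm = 40, alu_noise_fraction = 0.05,
                          loc_precision_nm = 10,
                          het_inner_nm = 100, het_outer_nm = 300,
                          het_ratio = 3, het_background_per_nm2 = 2e-4,
                          seed = NULL) {
  cl_assert(n_clusters >= 1, "n_clusters must be >= 1")
  cl_assert(het_inner_nm < het_outer_nm, "het_inner_nm must be < het_outer_nm")
  cl_assert(het_ratio >= 0 && het_background_per_nm2 >= 0,
            "heterochromatin intensities must be non-negative")
  cl_assert(points_per_cluster_mean >= points_per_cluster_min,
            "points_per_cluster_mean must be >= points_per_cluster_min")
  cl_assert(alu_noise_fraction >= 0 && alu_noise_fraction < 1,
            "alu_noise_fraction must be in [0, 1)")
  cl_assert(nucleus_radius_nm > het_outer_nm,
            "nucleus must be larger than the heterochromatin annulus")
  structure(list(n_clusters = as.integer(n_clusters),
                 nucleus_radius_nm = nucleus_radius_nm,
                 min_separation_nm = min_separation_nm,
                 points_per_cluster_min = as.integer(points_per_cluster_min),
                 points_per_cluster_mean = points_per_cluster_mean,
                 cluster_sigma_nm = cluster_sigma_nm,
                 alu_noise_fraction = alu_noise_fraction,
                 loc_precision_nm = loc_precision_nm,
                 het_inner_nm = het_inner_nm, het_outer_nm = het_outer_nm,
                 het_ratio = het_ratio,
                 het_background_per_nm2 = het_background_per_nm2,
                 seed = seed),
            class = "nucleus_model")
}

place_parents <- function(n, radius, min_sep, max_tries = 200000L) {
  px <- numeric(n); py <- numeric(n)
  placed <- 0L
  for (t in seq_len(max_tries)) {
    p <- runif_disc(1L, radius)
    if (placed == 0L ||
        min((px[seq_len(placed)] - p[1L])^2 +
              (py[seq_len(placed)] - p[2L])^2) >= min_sep^2) {
      placed <- placed + 1L
      px[placed] <- p[1L]; py[placed] <- p[2L]
      if (placed == n) return(cbind(x = px, y = py))
    }
  }
  cl_stop("could not place ", n, " cluster centres with separation ",
          min_sep, " nm inside the nucleus; reduce density")
}

#' Generate a two-channel synthetic nucleus
#'
#' @param model a [nucleus_model()].
#' @return list with `points` (localization table, channels `"alu"` and
#'   `"het"`, nucleus centred at the origin) and `truth`: `centers` (tibble
#'   `cluster`, `x_nm`, `y_nm`, `n_points`) and `membership` (per ALU-row
#'   planted cluster index, 0 for noise).
#' @export
generate_nucleus <- function(model) {
  cl_assert(inherits(model, "nucleus_model"), "model must be a nucleus_model")
  with_seed(model$seed, {
    R <- model$nucleus_radius_nm
    parents <- place_parents(model$n_clusters, R - model$het_outer_nm,
                             model$min_separation_nm)
    npts <- model$points_per_cluster_min +
      stats::rpois(model$n_clusters,
                   model$points_per_cluster_mean - model$points_per_cluster_min)
    member <- rep.int(seq_len(model$n_clusters), npts)
    n_clustered <- length(member)
    ax <- parents[member, 1L] + stats::rnorm(n_clustered, 0, model$cluster_sigma_nm)
    ay <- parents[member, 2L] + stats::rnorm(n_clustered, 0, model$cluster_sigma_nm)
    n_noise <- round(n_clustered * model$alu_noise_fraction /
                       (1 - model$alu_noise_fraction))
    if (n_noise > 0) {
      noise <- runif_disc(n_noise, R)
      ax <- c(ax, noise[, 1L]); ay <- c(ay, noise[, 2L])
      member <- c(member, rep.int(0L, n_noise))
    }
    ax <- ax + stats::rnorm(length(ax), 0, model$loc_precision_nm)
    ay <- ay + stats::rnorm(length(ay), 0, model$loc_precision_nm)

    # heterochromatin: exact inhomogeneous Poisson construction
    lam <- model$het_background_per_nm2
    nbg <- stats::rpois(1L, lam * pi * R^2)
    bg <- runif_disc(nbg, R)
    keep <- rep(TRUE, nbg)
    for (i in seq_len(model$n_clusters)) {
      d2 <- (bg[, 1L] - parents[i, 1L])^2 + (bg[, 2L] - parents[i, 2L])^2
      keep <- keep & d2 >= model$het_inner_nm^2
    }
    hx <- bg[keep, 1L]; hy <- bg[keep, 2L]
    extra_rate <- (model$het_ratio - 1) * lam *
      pi * (model$het_outer_nm^2 - model$het_inner_nm^2)
    cl_assert(extra_rate >= -1e-12 || model$het_ratio >= 0,
              "negative heterochromatin intensity")
    if (extra_rate > 0) {
      for (i in seq_len(model$n_clusters)) {
        ne <- stats::rpois(1L, extra_rate)
        if (ne > 0) {
          ann <- runif_annulus(ne, model$het_inner_nm, model$het_outer_nm,
                               parents[i, 1L], parents[i, 2L])
          hx <- c(hx, ann[, 1L]); hy <- c(hy, ann[, 2L])
        }
      }
    } else if (model$het_ratio < 1) {
      # thin the annulus band down to ratio * background
      for (i in seq_len(model$n_clusters)) {
        d2 <- (hx - parents[i, 1L])^2 + (hy - parents[i, 2L])^2
        band <- d2 >= model$het_inner_nm^2 & d2 < model$het_outer_nm^2
        drop <- band & stats::runif(length(hx)) > model$het_ratio
        hx <- hx[!drop]; hy <- hy[!drop]
      }
    }
    x <- c(ax, hx); y <- c(ay, hy)
    channel <- c(rep.int("alu", length(ax)), rep.int("het", length(hx)))
    points <- localization_set(
      frame = rep.int(0L, length(x)), channel = channel, x_nm = x, y_nm = y,
      photons = rep.int(1000, length(x)),
      sigma_x_nm = rep.int(0, length(x)), sigma_y_nm = rep.int(0, length(x)),
      precision_x_nm = rep.int(model$loc_precision_nm, length(x)),
      precision_y_nm = rep.int(model$loc_precision_nm, length(x)),
      background = rep.int(0, length(x)))
    list(points = points,
         truth = list(centers = tibble::tibble(cluster = seq_len(model$n_clusters),
                                               x_nm = parents[, 1L],
                                               y_nm = parents[, 2L],
                                               n_points = npts),
                      membership = member))
  })
}

#' Planted-repeat genome model
#'
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#' @param consensus consensus sequence to plant (default [alu_consensus()]).
#' @param n_copies copies per chromosome (single value, recycled).
#' @param substitution_rate per-site substitution probability in each
#'   planted copy, in `[0, 0.3]` (default 0).
#' @param base_composition background probabilities for A, C, G, T
#'   (default uniform).
#' @param seed RNG seed.
#' @return a `repeat_genome_model` list.
#' @export
repeat_genome_model <- function(chrom_lengths, consensus = alu_consensus(),
                                n_copies = 25L, substitution_rate = 0,
                                base_composition = c(A = 0.25, C = 0.25,
                                                     G = 0.25, T = 0.25),
                                seed = NULL) {
  cl_assert(!is.null(names(chrom_lengths)) && all(chrom_lengths > 0),
            "chrom_lengths must be a named vector of positive lengths")
  cl_assert(substitution_rate >= 0 && substitution_rate <= 0.3,
            "substitution_rate must be in [0, 0.3]")
  n_copies <- rep_len(as.integer(n_copies), length(chrom_lengths))
  cl_assert(all(n_copies * nchar(consensus) < chrom_lengths),
            "total planted copy length must be below each chromosome length")
  structure(list(chrom_lengths = chrom_lengths, consensus = toupper(consensus),
                 n_copies = n_copies, substitution_rate = substitution_rate,
                 base_composition = base_composition / sum(base_composition),
                 seed = seed),
            class = "repeat_genome_model")
}

# Uniform non-overlapping placement via the spacing construction: sample n
# starts in the length reduced by n copy-lengths, sort, then shift the i-th
# start by (i-1) copy lengths. Equivalent to uniform sampling conditioned on
# no overlap, and always succeeds when the copies fit.
sample_nonoverlapping_starts <- function(n, chrom_len, copy_len) {
  if (n == 0L) return(integer(0))
  slack <- chrom_len - n * copy_len
  cl_assert(slack >= 0, "cannot place ", n, " copies of length ", copy_len,
            " in a chromosome of length ", chrom_len)
  raw <- sort(sample.int(slack + 1L, n, replace = TRUE)) - 1L  # 0-based
  raw + (seq_len(n) - 1L) * copy_len
}

mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(bases)) < rate)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
  }
  paste(bases, collapse = "")
}

#' Generate a genome with planted repeat copies
#'
#' Background bases are i.i.d. from `base_composition`; planted copies of
#' the consensus (each independently mutated at `substitution_rate`) are
#' placed uniformly without overlap; every copy is recorded in a BED-style
#' truth table.
#'
#' @param model a [repeat_genome_model()].
#' @return list with `genome` (a `Biostrings::DNAStringSet`) and `bed`
#'   (tibble `chrom`, `start`, `end`, `name`, 0-based half-open).
#' @export
generate_genome <- function(model) {
  cl_assert(inherits(model, "repeat_genome_model"),
            "model must be a repeat_genome_model")
  with_seed(model$seed, {
    L <- nchar(model$consensus)
    seqs <- character(length(model$chrom_lengths))
    beds <- list()
    for (i in seq_along(model$chrom_lengths)) {
      chrom <- names(model$chrom_lengths)[i]
      len <- model$chrom_lengths[[i]]
      bases <- sample(names(model$base_composition), len, replace = TRUE,
                      prob = model$base_composition)
      starts <- sample_nonoverlapping_starts(model$n_copies[i], len, L)
      for (s in starts) {
        copy <- mutate_sequence(model$consensus, model$substitution_rate)
        bases[(s + 1L):(s + L)] <- strsplit(copy, "", fixed = TRUE)[[1L]]
      }
      seqs[i] <- paste(bases, collapse = "")
      if (length(starts)) {
        beds[[length(beds) + 1L]] <- tibble::tibble(
          chrom = chrom, start = starts, end = starts + L,
          name = sprintf("%s_copy%03d", chrom, seq_along(starts)))
      }
    }
    names(seqs) <- names(model$chrom_lengths)
    bed <- if (length(beds)) do.call(rbind, beds) else
      tibble::tibble(chrom = character(), start = integer(),
                     end = integer(), name = character())
    list(genome = Biostrings::DNAStringSet(seqs), bed = bed)
  })
}

#' Generate a synthetic dose-response count series
#'
#' Per-cell counts follow `round(N(D) + noise)`, floored at 0, with
#' `N(D) = a D^2 + b D + c` and Gaussian (default) or Poisson noise.
#' Defaults are the reference calibration curve (a = 3054, b = -11480,
#' c = 21390) over 0-2 Gy with 35 cells per dose.
#'
#' @param a,b,c quadratic model coefficients.
#' @param doses dose values in Gy (default `c(0, 0.1, 0.5, 1, 2)`).
#' @param n_cells_per_dose cells per dose (default 35).
#' @param noise_sigma Gaussian noise SD in counts (default 500).
#' @param noise "gaussian" (default) or "poisson" (ignores `noise_sigma`).
#' @param seed RNG seed.
#' @return tibble with `dose_gy`, `cell_id`, `count`.
#' @export
generate_dose_series <- function(a = 3054, b = -11480, c = 21390,
                                 doses = c(0, 0.1, 0.5, 1, 2),
                                 n_cells_per_dose = 35L, noise_sigma = 500,
                                 noise = c("gaussian", "poisson"),
                                 seed = NULL) {
  noise <- match.arg(noise)
  mu <- a * doses^2 + b * doses + c
  cl_assert(all(mu > 0), "predicted mean count must be positive at every dose")
  with_seed(seed, {
    rows <- lapply(seq_along(doses), function(i) {
      counts <- if (noise == "gaussian") {
        pmax(0, round(mu[i] + stats::rnorm(n_cells_per_dose, 0, noise_sigma)))
      } else {
        stats::rpois(n_cells_per_dose, mu[i])
      }
      tibble::tibble(dose_gy = doses[i], cell_id = seq_len(n_cells_per_dose),
                     count = as.numeric(counts))
    })
    do.call(rbind, rows)
  })
}
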