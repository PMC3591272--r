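#' Ground truth for a synthetic reporter library
#'
#' Bundles every generative parameter the synthetic-data functions share,
#' so that the data and the truth used to score recovery always travel
#' together. Defaults emulate the study conditions of an 85-strain yeast
#' 3' end reporter library: a planted A/T-content effect in a 30-bp
#' window centered 40 bp upstream of the main polyadenylation site, an
#' expression range spanning roughly twelve-fold, logistic growth with a
#' ~100-minute doubling time, and gamma-distributed bursty single-cell
#' expression.
#'
#' @param window_center planted effect window center, bp relative to the
#'   main cleavage site (negative = upstream; default -40).
#' @param window_size planted window size in bp (default 30, >= 1).
#' @param beta0,beta1 intercept and slope of expression (a.u. per OD per
#'   second) against the window A/T fraction. Defaults (-5.58, 20) put
#'   the 85-strain library at about a twelve-fold max/min expression
#'   ratio: planted window A/T fractions snap to multiples of
#'   1/window_size, so the extremes sit at 10/30 and 28/30 and
#'   `(28/30 * beta1 + beta0) / (10/30 * beta1 + beta0) = 12` at
#'   `beta0 = -5.58`.
#' @param sigma_e expression noise sd (a.u.; default 0.15).
#' @param at_range range of planted per-construct window A/T fractions;
#'   constructs are spaced evenly across it (default c(0.35, 0.95)).
#' @param site_noise sd (bp) of the discretized-normal placement of
#'   satellite cleavage sites around the main site (default 15).
#' @param growth list with `K` (carrying capacity, OD), `od0` (initial
#'   OD), `r` (per-second logistic rate), `lag` (lag-phase duration, s).
#' @param burst list with `a` (bursts per protein lifetime) and `b`
#'   (proteins per burst, a.u.).
#' @param seed integer RNG seed recorded with the truth.
#' @return object of class `LibraryTruth`.
#' @export
library_truth <- function(window_center = -40L, window_size = 30L,
                          beta0 = -5.58, beta1 = 20, sigma_e = 0.15,
                          at_range = c(0.35, 0.95), site_noise = 15,
                          growth = list(K = 1.0, od0 = 0.05,
                                        r = log(2) / 6000, lag = 7200),
                          burst = list(a = 10, b = 100),
                          seed = NULL) {
  stopifnot(window_size >= 1L, sigma_e >= 0,
            length(at_range) == 2L, at_range[1] < at_range[2],
            at_range[1] >= 0, at_range[2] <= 1)
  stopifnot(growth$K > growth$od0, growth$od0 > 0, growth$r > 0,
            growth$lag >= 0)
  stopifnot(burst$a > 0, burst$b > 0)
  structure(
    list(window_center = as.integer(window_center),
         window_size = as.integer(window_size),
         beta0 = beta0, beta1 = beta1, sigma_e = sigma_e,
         at_range = at_range, site_noise = site_noise,
         growth = growth, burst = burst, seed = seed,
         constructs = NULL),
    class = "LibraryTruth"
  )
}

# Sample one construct's cleavage-site distribution: a main site plus 0-3
# satellites placed by discretized-normal jitter, with the main site
# holding 55-85% of the weight.
sample_site_distribution <- function(main, len, site_noise) {
  n_sat <- sample(0:3, 1L)
  sat <- unique(main + round(rnorm(n_sat, 0, site_noise)))
  sat <- sat[sat != main & sat >= 60L & sat <= len - 1L]
  w_main <- runif(1, 0.55, 0.85)
  if (length(sat)) {
    w_sat <- runif(length(sat))
    w_sat <- (1 - w_main) * w_sat / sum(w_sat)
    pos <- c(main, sat)
    w <- c(w_main, w_sat)
  } else {
    pos <- main
    w <- 1
  }
  o <- order(pos)
  data.frame(position = as.integer(pos[o]), weight = w[o] / sum(w))
}

#' Generate a synthetic 3' end construct library with planted truth
#'
#' Generates `n` constructs (200-1000 bp, uniform 25%-per-base background
#' composition) each carrying a main cleavage site with satellite sites,
#' and plants an A/T-content effect: the A/T fraction of the effect
#' window (size `truth$window_size`, centered `truth$window_center` bp
#' from the main site) is assigned on an even per-construct grid across
#' `truth$at_range`, and expression is
#' `beta0 + beta1 * AT + Normal(0, sigma_e)` truncated at 0. With the
#' defaults this reproduces the study conditions: 85 strains spanning a
#' continuous greater-than-ten-fold expression range driven by upstream
#' A/T content.
#'
#' @param n number of constructs (>= 3; default 85, the library size).
#' @param truth a [library_truth()] object.
#' @param seed RNG seed; a fixed seed gives an identical library on
#'   repeated calls.
#' @return list with `constructs` (each carrying its true site
#'   distribution as attribute `"sites"`) and `truth` (the input truth
#'   with a per-construct `constructs` data.frame filled in: planted
#'   window A/T, window coordinates, main site, expression).
#' @export
generate_construct_library <- function(n = 85L, truth = library_truth(),
                                       seed = 1L) {
  stopifnot(n >= 3L)
  with_seed(seed, {
    w <- truth$window_size
    ctr <- truth$window_center
    at_grid <- sample(seq(truth$at_range[1], truth$at_range[2],
                          length.out = n))
    lens <- sample(200:1000, n, replace = TRUE)
    constructs <- vector("list", n)
    info <- vector("list", n)
    for (i in seq_len(n)) {
      len <- lens[i]
      repeat {
        main <- sample(100:(len - 50L), 1L)
        win <- anchored_window(ctr, w, main)
        if (win[1] >= 0L && win[2] <= len) break
        len <- min(1000L, len + 100L)  # never silently clip: grow instead
      }
      bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      # plant the window composition exactly
      n_at <- round(w * at_grid[i])
      idx <- win[1]:(win[2] - 1L) + 1L
      at_pos <- sample(idx, n_at)
      bases[at_pos] <- sample(c("A", "T"), n_at, replace = TRUE)
      bases[setdiff(idx, at_pos)] <- sample(c("C", "G"), w - n_at,
                                            replace = TRUE)
      seq_chr <- paste(bases, collapse = "")
      at_real <- mean(bases[idx] %in% c("A", "T"))
      expr <- max(0, truth$beta0 + truth$beta1 * at_real +
                    rnorm(1, 0, truth$sigma_e))
      sites <- sample_site_distribution(main, len, truth$site_noise)
      cons <- construct(
        gene_id = sprintf("SYN%03d", i), sequence = seq_chr,
        cleavage_site = main,
        orientation = sample(c("tandem", "convergent"), 1L),
        intergenic_length = len, expression = expr
      )
      attr(cons, "sites") <- sites
      constructs[[i]] <- cons
      info[[i]] <- data.frame(
        gene_id = cons$gene_id, length = len, main_site = main,
        window_start = win[1], window_end = win[2],
        at_planted = at_grid[i], at_realized = at_real,
        expression = expr, n_sites = nrow(sites)
      )
    }
    names(constructs) <- vapply(constructs, `[[`, "", "gene_id")
    truth$constructs <- do.call(rbind, info)
    truth$site_distributions <- lapply(constructs, attr, "sites")
    truth$seed <- seed
    list(constructs = constructs, truth = truth)
  })
}

# Logistic OD with a lag phase, and its exact time integral (used so that
# noiseless simulated fluorescence is an exact model inversion).
logistic_od <- function(t, g) {
  tt <- pmax(0, t - g$lag)
  g$K * g$od0 * exp(g$r * tt) / (g$K - g$od0 + g$od0 * exp(g$r * tt))
}

logistic_od_integral <- function(t, g) {
  tt <- pmax(0, t - g$lag)
  g$od0 * pmin(t, g$lag) +
    (g$K / g$r) * log((g$K - g$od0 + g$od0 * exp(g$r * tt)) / g$K)
}

#' Simulate plate-fluorometer time courses
#'
#' Forward model inverted by the plate-reader pipeline: logistic growth
#' `OD(t) = K / (1 + ((K - od0)/od0) exp(-r t))` (after a lag), protein
#' accumulation `dY/dt = P_i OD(t)` for each strain's true production rate
#' `P_i` (proteins are stable, so no degradation term), a constant
#' reference production rate for mCherry, additive backgrounds (media OD,
#' autofluorescence proportional to OD plus a constant), multiplicative
#' Gaussian measurement noise, and sparse spike outliers. Background wells
#' for each role are emitted alongside the samples, so the full
#' subtraction / outlier-removal / segmentation / integration pipeline
#' can be exercised end to end.
#'
#' @param strains data.frame with columns `strain_id` and `production`
#'   (true YFP production rates, a.u. per OD per second; must be > 0).
#' @param truth a [library_truth()] object (growth parameters are taken
#'   from it).
#' @param seed RNG seed.
#' @param noise_cv multiplicative measurement noise CV (default 0.01).
#' @param spike_rate per-point probability of a spike outlier
#'   (default 0.01).
#' @param n_replicates replicate wells per strain (default 3, matching
#'   triplicate plate measurements).
#' @param interval sampling interval in seconds (default 1200, i.e. every
#'   20 minutes).
#' @param duration total time span in seconds (default 24 h).
#' @param p_ref mCherry (reference channel) production rate shared by all
#'   strains (default 2).
#' @return list with `samples` (list of [time_course()]), `backgrounds`
#'   (role-keyed list for [subtract_background()]) and `truth` (planted
#'   production rates, spike positions as a data.frame, background
#'   parameters).
#' @export
simulate_plate_timecourses <- function(strains, truth = library_truth(),
                                       seed = 1L, noise_cv = 0.01,
                                       spike_rate = 0.01,
                                       n_replicates = 3L,
                                       interval = 1200, duration = 86400,
                                       p_ref = 2) {
  strains <- as.data.frame(strains)
  stopifnot(all(c("strain_id", "production") %in% names(strains)))
  if (any(strains$production <= 0)) {
    stop_format("non-positive production rate for strain(s): %s",
                paste(strains$strain_id[strains$production <= 0], collapse = ", "))
  }
  g <- truth$growth
  bg <- list(od_media = 0.04, yfp_auto = 30, yfp_base = 50,
             mch_auto = 15, mch_base = 40)
  times <- seq(0, duration, by = interval)
  od_true <- logistic_od(times, g)
  int_true <- logistic_od_integral(times, g)
  with_seed(seed, {
    spikes <- list()
    noisy <- function(x, well, channel) {
      x <- x * (1 + rnorm(length(x), 0, noise_cv))
      hit <- which(runif(length(x)) < spike_rate)
      if (length(hit)) {
        x[hit] <- x[hit] * runif(length(hit), 3, 8)
        spikes[[length(spikes) + 1L]] <<- data.frame(
          well = well, channel = channel, index = hit)
      }
      x
    }
    make_well <- function(well, strain, p_yfp, p_mch, grows = TRUE) {
      od <- if (grows) od_true + bg$od_media else rep(bg$od_media, length(times))
      odg <- if (grows) od_true else numeric(length(times))
      intg <- if (grows) int_true else numeric(length(times))
      yfp <- p_yfp * intg + bg$yfp_auto * odg + bg$yfp_base
      mch <- p_mch * intg + bg$mch_auto * odg + bg$mch_base
      time_course(well, strain, times,
                  noisy(od, well, "od"),
                  noisy(yfp, well, "yfp"),
                  noisy(mch, well, "mcherry"))
    }
    samples <- list()
    for (i in seq_len(nrow(strains))) {
      for (r in seq_len(n_replicates)) {
        well <- sprintf("%s_r%d", strains$strain_id[i], r)
        samples[[well]] <- make_well(well, strains$strain_id[i],
                                     strains$production[i], p_ref)
      }
    }
    # background roles are measured in replicate wells too, and averaged
    bg_reps <- function(prefix, strain, p_yfp, p_mch, grows = TRUE) {
      average_timecourses(lapply(seq_len(n_replicates), function(r) {
        make_well(sprintf("%s_r%d", prefix, r), strain, p_yfp, p_mch,
                  grows = grows)
      }))
    }
    backgrounds <- list(
      media_blank = bg_reps("BLANK", "media", 0, 0, grows = FALSE),
      # mCherry-only strain: provides the YFP background curve
      yfp_background_strain = bg_reps("YBG", "mcherry_only", 0, p_ref),
      # YFP-only strain: provides the mCherry background curve
      mcherry_background_strain = bg_reps("MBG", "yfp_only",
                                          stats::median(strains$production), 0)
    )
    list(
      samples = samples, backgrounds = backgrounds,
      truth = list(
        production = setNames(strains$production, strains$strain_id),
        p_ref = p_ref, growth = g, background = bg,
        noise_cv = noise_cv,
        spikes = if (length(spikes)) do.call(rbind, spikes) else
          data.frame(well = character(), channel = character(),
                     index = integer()),
        times = times
      )
    )
  })
}

#' Simulate 3'RACE reads for one construct
#'
#' Reads mimic the poly(T) priming chemistry on the sequenced strand:
#' a 12-nt random UMI, a poly(T) block of at least 18 nt, then the
#' reverse complement of the transcript 3' end, whose last transcribed
#' base is drawn from the construct's true cleavage-site distribution.
#' The per-read true site is recorded in the FASTQ description for oracle
#' checks.
#'
#' @param construct a [construct()] carrying its site distribution as
#'   attribute `"sites"` (as produced by [generate_construct_library()]),
#'   or supply `sites` explicitly.
#' @param n_reads number of reads (>= 1).
#' @param tail_len mean poly(T) block length in nt (>= 18; default 25).
#' @param site_noise per-read discretized-normal jitter sd (bp) around the
#'   sampled site (default 0).
#' @param seed RNG seed.
#' @param sites data.frame(position, weight) overriding the attribute.
#' @param error_rate uniform substitution rate per base (default 0).
#' @param defect_rate fraction of reads rendered defective -- tail
#'   replaced by random sequence ("no_tail") or truncated ("too_short") --
#'   to exercise the rejection accounting (default 0).
#' @return named character vector of read sequences; names are FASTQ
#'   headers `read<i> gene=<id> true_site=<pos>`.
#' @export
simulate_race_reads <- function(construct, n_reads, tail_len = 25,
                                site_noise = 0, seed = 1L, sites = NULL,
                                error_rate = 0, defect_rate = 0) {
  stopifnot(n_reads >= 1L, tail_len >= 18)
  sites <- sites %||% attr(construct, "sites")
  if (is.null(sites)) {
    stop_format("construct '%s' has no cleavage-site distribution",
                construct$gene_id)
  }
  if (any(sites$position < 20L)) {
    stop_format("construct '%s': cleavage site < 20 bp from sequence start is unmappable",
                construct$gene_id)
  }
  len <- nchar(construct$sequence)
  with_seed(seed, {
    s <- sites$position[sample.int(nrow(sites), n_reads, replace = TRUE,
                                   prob = sites$weight)]
    if (site_noise > 0) {
      s <- pmin(pmax(s + round(rnorm(n_reads, 0, site_noise)), 20L),
                len - 1L)
    }
    frag_len <- sample(60:100, n_reads, replace = TRUE)
    a <- pmax(0L, s - frag_len + 1L)
    frags <- substring(construct$sequence, a + 1L, s + 1L)
    tails <- strrep("T", 18L + rpois(n_reads, tail_len - 18))
    umis <- vapply(seq_len(n_reads), function(i) {
      paste(sample(c("A", "C", "G", "T"), 12L, replace = TRUE),
            collapse = "")
    }, "")
    reads <- paste0(umis, tails, revcomp_chr(frags))
    if (error_rate > 0) {
      reads <- vapply(reads, function(rd) {
        ch <- strsplit(rd, "")[[1]]
        hit <- which(runif(length(ch)) < error_rate)
        if (length(hit)) ch[hit] <- sample(c("A", "C", "G", "T"),
                                           length(hit), replace = TRUE)
        paste(ch, collapse = "")
      }, "", USE.NAMES = FALSE)
    }
    if (defect_rate > 0) {
      bad <- which(runif(n_reads) < defect_rate)
      for (i in bad) {
        if (runif(1) < 0.5) {  # destroy the tail
          body <- substr(reads[i], 13L, nchar(reads[i]))
          reads[i] <- paste0(substr(reads[i], 1L, 12L),
                             chartr("T", "G", body))
        } else {               # truncate below the minimum usable length
          reads[i] <- substr(reads[i], 1L, 12L + 8L + 10L)
        }
      }
      attr_bad <- bad
    } else attr_bad <- integer()
    names(reads) <- sprintf("read%06d gene=%s true_site=%d",
                            seq_len(n_reads), construct$gene_id, s)
    attr(reads, "true_sites") <- s
    attr(reads, "defective") <- attr_bad
    reads
  })
}

#' Simulate a single-cell fluorescence population
#'
#' Per-cell YFP follows the gamma burst model: `Gamma(shape = a,
#' scale = b)` (a = bursts per protein lifetime, b = proteins per burst)
#' multiplied by a unit-mean lognormal extrinsic factor shared with the
#' mCherry channel; forward/side scatter are lognormal; a `spore_frac`
#' fraction of cells forms a low-scatter, low-fluorescence spore cluster.
#' With `extrinsic_cv = 0` and `spore_frac = 0` the YFP distribution is
#' exactly Gamma(a, b).
#'
#' @param a burst frequency (> 0).
#' @param b burst size, a.u. (> 0).
#' @param n_cells population size (>= 100).
#' @param extrinsic_cv CV of the shared extrinsic factor (default 0).
#' @param spore_frac fraction of spore-like cells, in [0, 0.5)
#'   (default 0).
#' @param seed RNG seed.
#' @param strain_id,condition labels stored on the population.
#' @return object of class `CellPopulation`: a data.frame with columns
#'   `fsc`, `ssc`, `yfp`, `mcherry` and attributes `strain_id`,
#'   `condition`, `spore` (logical truth flags).
#' @export
simulate_cell_population <- function(a, b, n_cells = 10000L,
                                     extrinsic_cv = 0, spore_frac = 0,
                                     seed = 1L, strain_id = "synthetic",
                                     condition = NA_real_) {
  if (!(a > 0) || !(b > 0)) stop_format("burst parameters must be positive")
  if (n_cells < 100L) stop_format("need at least 100 cells")
  if (spore_frac < 0 || spore_frac >= 0.5) {
    stop_format("spore_frac must be in [0, 0.5)")
  }
  with_seed(seed, {
    yfp <- rgamma(n_cells, shape = a, scale = b)
    mch <- rgamma(n_cells, shape = 30, scale = 50)
    if (extrinsic_cv > 0) {
      sdl <- sqrt(log(1 + extrinsic_cv^2))
      ext <- rlnorm(n_cells, meanlog = -sdl^2 / 2, sdlog = sdl)
      yfp <- yfp * ext
      mch <- mch * ext
    }
    fsc <- rlnorm(n_cells, meanlog = log(100), sdlog = 0.25)
    ssc <- rlnorm(n_cells, meanlog = log(80), sdlog = 0.30)
    spore <- rep(FALSE, n_cells)
    if (spore_frac > 0) {
      spore <- runif(n_cells) < spore_frac
      ns <- sum(spore)
      fsc[spore] <- fsc[spore] * 0.15 * exp(rnorm(ns, 0, 0.1))
      ssc[spore] <- ssc[spore] * 0.3 * exp(rnorm(ns, 0, 0.1))
      yfp[spore] <- yfp[spore] * 0.05
      mch[spore] <- mch[spore] * 0.05
    }
    structure(
      data.frame(fsc = fsc, ssc = ssc, yfp = yfp, mcherry = mch),
      strain_id = strain_id, condition = condition, spore = spore,
      burst = list(a = a, b = b), class = c("CellPopulation", "data.frame")
    )
  })
}

#' Write a cell population to TSV
#'
#' @param pop a [simulate_cell_population()] object (or any data.frame
#'   with the four channels).
#' @param path output path.
#' @export
write_cell_table <- function(pop, path) {
  data.table::fwrite(as.data.frame(pop)[, c("fsc", "ssc", "yfp", "mcherry")],
                     path, sep = "\t")
  invisible(path)
}

#' Read a cell population from TSV (or FCS-exported CSV)
#'
#' @param path file with columns `fsc`, `ssc`, `yfp`, `mcherry`
#'   (case-insensitive; FCS channel aliases `FSC-A` etc. are accepted).
#' @param strain_id,condition labels to attach.
#' @return a `CellPopulation`.
#' @export
read_cell_table <- function(path, strain_id = NA_character_,
                            condition = NA_real_) {
  dt <- as.data.frame(data.table::fread(path))
  nm <- tolower(gsub("-A$", "", names(dt), ignore.case = TRUE))
  names(dt) <- nm
  required <- c("fsc", "ssc", "yfp", "mcherry")
  missing_cols <- setdiff(required, nm)
  if (length(missing_cols)) {
    stop_format("cell table '%s' is missing channel(s): %s", path,
                paste(missing_cols, collapse = ", "))
  }
  if (any(vapply(dt[required], function(x) any(x < 0), TRUE))) {
    stop_format("cell table '%s': negative channel values", path)
  }
  if (!nrow(dt)) stop_format("cell table '%s' is empty", path)
  structure(dt[required], strain_id = strain_id, condition = condition,
            class = c("CellPopulation", "data.frame"))
}
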