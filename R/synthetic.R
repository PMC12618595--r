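# Synthetic cohort generator. Emulates, at the matrix level, the study
# conditions the analysis assumes: 126 healthy adults (18-50) and 5
# psychosis patients (18-35, integer PANSS scores), five structural
# edge-weight variants with visibly distinct weight distributions, a shared
# Euclidean-distance geometry, and band-specific functional matrices built
# from a known linear ground-truth law on z-scored negated SPL/SI/ED
# predictors, with per-band noise largest in delta. Everything is a pure
# function of (config, seed).

#' Ground-truth SC-to-FC mapping for the synthetic generator
#'
#' The generated FC for band `b` at edge `e` is
#' `beta0 + b_spl * (-z(SPL)) + b_si * (-z(SI)) + b_ed * (-z(ED)) + noise`,
#' affinely rescaled into `[0, 1]`. Negation encodes that shorter paths,
#' lower search information and shorter distances mean stronger coupling.
#' Per-band noise SDs are on the scale of the (unit-variance-ish) linear
#' predictor and default to a strictly decreasing sequence from delta to
#' beta, so delta has the largest inter-subject edge variability and the
#' lowest analytical-model accuracy, and the higher bands are predicted
#' best.
#'
#' @param coefficients Named list per band, each `c(beta0, spl, si, ed)`.
#' @param noise_sd Named numeric vector of per-band edge-noise SDs.
#' @param individuality_sd SD of the per-subject jitter applied to the
#'   coefficients *and* (scaled) to the subject-specific structural weight
#'   jitter -- individuality of the SC-FC relationship is carried by the
#'   subject's own structural fingerprint, which is what the shuffling
#'   analysis can detect.
#' @param patient_shift Named list per band of additive coefficient
#'   perturbations for the psychosis group. The defaults strengthen the
#'   delta-band coupling and weaken alpha/beta, so the patient group's
#'   *relationship* diverges while its matrices follow the healthy law.
#' @return An object of class `scfc_mapping`.
#' @export
gt_mapping <- function(coefficients = NULL, noise_sd = NULL,
                       individuality_sd = 0.1, patient_shift = NULL) {
  base <- c(beta0 = 0, spl = 0.5, si = 0.3, ed = 0.2)
  if (is.null(coefficients))
    coefficients <- setNames(rep(list(base), 4), FC_BANDS)
  if (is.null(noise_sd))
    noise_sd <- c(delta = 2.8, theta = 2.0, alpha = 1.5, beta = 1.35)
  if (is.null(patient_shift))
    patient_shift <- list(
      delta = c(beta0 = 0, spl = 0.35, si = 0.20, ed = 0.10),
      theta = c(beta0 = 0, spl = 0, si = 0, ed = 0),
      alpha = c(beta0 = 0, spl = -0.30, si = -0.18, ed = -0.12),
      beta  = c(beta0 = 0, spl = -0.30, si = -0.18, ed = -0.12))
  stopifnot(all(FC_BANDS %in% names(coefficients)),
            all(FC_BANDS %in% names(noise_sd)),
            all(FC_BANDS %in% names(patient_shift)),
            all(noise_sd >= 0), individuality_sd >= 0)
  if (!all(is.finite(unlist(coefficients))) ||
      !all(is.finite(unlist(patient_shift))))
    stop_scfc("scfc_value_error", "mapping parameters must be finite")
  structure(list(coefficients = coefficients, noise_sd = noise_sd,
                 individuality_sd = individuality_sd,
                 patient_shift = patient_shift),
            class = "scfc_mapping")
}

#' Synthetic-cohort configuration
#'
#' Defaults reproduce the study conditions: 126 healthy subjects aged
#' 18-50, 5 patients aged 18-35, an 84-region parcellation, structural
#' density 0.35.
#'
#' @param n_nodes Region count (default 84).
#' @param n_healthy,n_patients Group sizes.
#' @param age_healthy,age_patient Age ranges (years).
#' @param sc_density Expected fraction of present structural edges.
#' @param subject_jitter Baseline SD of the per-subject structural weight
#'   jitter (latent/log scale).
#' @param topo_flip Per-edge probability that a subject's topology deviates
#'   from the cohort backbone.
#' @param dist_lambda Length scale (mm) of the exponential distance decay of
#'   connection probability.
#' @param mapping A [gt_mapping()].
#' @param mapping_source SC variant whose predictors generate the FC.
#' @param panss_coupling If nonzero, injects a monotone link between patient
#'   PANSS totals and the strength of the patient coefficient perturbation,
#'   so symptom-severity correlations become detectable.
#' @param seed Mandatory integer master seed.
#' @return An object of class `scfc_synth_config`.
#' @export
synth_config <- function(n_nodes = 84, n_healthy = 126, n_patients = 5,
                         age_healthy = c(18, 50), age_patient = c(18, 35),
                         sc_density = 0.35, subject_jitter = 0.08,
                         topo_flip = 0.02, dist_lambda = 40,
                         mapping = gt_mapping(), mapping_source = "FA",
                         panss_coupling = 0, seed) {
  if (missing(seed)) stop_scfc("scfc_config_error", "seed is mandatory")
  stopifnot(n_nodes >= 3, n_healthy >= 1, n_patients >= 0,
            sc_density > 0, sc_density <= 1, subject_jitter >= 0,
            inherits(mapping, "scfc_mapping"),
            mapping_source %in% SC_VARIANTS)
  structure(as.list(environment()), class = "scfc_synth_config")
}

subseed <- function(seed, offset) (as.integer(seed) + offset) %% .Machine$integer.max

#' Generate a parcellation with hemispheric geometry
#'
#' Region centroids are sampled uniformly inside two mirrored ellipsoids
#' (left/right hemisphere, semi-axes 25 x 35 x 30 mm, centers at x = -30 and
#' +30), deterministic given the seed. The Euclidean-distance matrix between
#' centroids is shared by every subject of a cohort.
#'
#' @param n Region count, at least 3.
#' @param seed Integer seed.
#' @return List with `parcellation` and `ed` (an ED `scfc_matrix`).
#' @export
generate_parcellation <- function(n, seed) {
  if (n < 3) stop_scfc("scfc_config_error", "need at least 3 regions")
  set.seed(subseed(seed, 1L))
  n_left <- ceiling(n / 2)
  sample_ellipsoid <- function(k, center) {
    semi <- c(25, 35, 30)
    out <- matrix(NA_real_, k, 3)
    got <- 0
    while (got < k) {
      cand <- matrix(runif(3 * k, -1, 1), ncol = 3)
      keep <- rowSums(cand^2) <= 1
      take <- min(k - got, sum(keep))
      if (take > 0) {
        rows <- which(keep)[seq_len(take)]
        out[got + seq_len(take), ] <-
          sweep(cand[rows, , drop = FALSE] %*% diag(semi), 2, center, "+")
        got <- got + take
      }
    }
    out
  }
  left <- sample_ellipsoid(n_left, c(-30, 0, 0))
  right <- sample_ellipsoid(n - n_left, c(30, 0, 0))
  centroids <- rbind(left, right)
  labels <- c(sprintf("L_%02d", seq_len(n_left)),
              sprintf("R_%02d", seq_len(n - n_left)))
  parc <- parcellation(labels, centroids)
  ed <- conn_matrix(as.matrix(stats::dist(centroids)), "ED", parc = parc)
  list(parcellation = parc, ed = ed)
}

# Cohort-level structural backbone and base edge weights, shared by all
# subjects so that inter-subject connectome similarity is high (as observed
# in healthy cohorts); subjects deviate by weight jitter and sparse edge
# flips.
make_sc_base <- function(ed, density, lambda, seed) {
  set.seed(subseed(seed, 2L))
  d <- upper_triangle(ed)
  p0 <- exp(-d / lambda)
  f <- function(cc) mean(pmin(1, cc * p0)) - density
  cc <- uniroot(f, c(1e-6, 1e6))$root
  p <- pmin(1, cc * p0)
  n <- ed$parcellation$n
  backbone <- runif(length(d)) < p
  backbone <- ensure_connected(backbone, d, n)
  m <- length(d)
  # region volumes (mm^3) for the NS/v normalization
  vols <- rlnorm(n, meanlog = log(5000), sdlog = 0.3)
  pair_idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pair_idx <- pair_idx[order(pair_idx[, 1], pair_idx[, 2]), , drop = FALSE]
  vol_sum <- vols[pair_idx[, 1]] + vols[pair_idx[, 2]]
  # NS: heavy-tailed log-normal, decaying with distance
  ns_meanlog <- 5 - d / 40
  # bounded microstructural variants: correlated latents -> beta quantiles
  shared <- rnorm(m)
  lat <- list(FA  = sqrt(0.6) * shared + sqrt(0.4) * rnorm(m),
              iRD = sqrt(0.6) * shared + sqrt(0.4) * rnorm(m),
              FRt = sqrt(0.6) * shared + sqrt(0.4) * rnorm(m))
  shapes <- list(FA = c(9, 11), iRD = c(11, 9), FRt = c(7, 13))
  list(backbone = backbone, d = d, n = n, vol_sum = vol_sum,
       ns_meanlog = ns_meanlog, ns_sdlog = 0.9, lat = lat, shapes = shapes,
       p = p)
}

# Keep the topology connected: greedily join components with the shortest
# available inter-component edge (deterministic).
ensure_connected <- function(edges, d, n) {
  adj <- from_upper_triangle(as.numeric(edges), n)
  comp <- components_of(adj)
  while (max(comp) > 1) {
    best <- Inf; best_ij <- NULL
    idx <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      idx <- idx + 1
      if (comp[i] != comp[j] && d[idx] < best) {
        best <- d[idx]; best_ij <- idx
      }
    }
    edges[best_ij] <- TRUE
    adj <- from_upper_triangle(as.numeric(edges), n)
    comp <- components_of(adj)
  }
  edges
}

components_of <- function(adj) {
  n <- nrow(adj)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      nb <- which(adj[u, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Generate one subject's five structural matrices
#'
#' All five edge-weight variants (NS, NS/v, FA, iRD, FRt) share one binary
#' topology per subject: the cohort backbone (distance-decaying edge
#' probability calibrated to the target density) with sparse subject-specific
#' edge flips. NS is heavy-tailed log-normal decaying with distance; NS/v
#' divides NS by the simulated region-volume pair sums; FA, iRD and FRt are
#' bounded unimodal draws on (0, 1) with variant-specific means and mutual
#' correlation about 0.6. `subject_jitter` is the SD of the subject-specific
#' latent jitter (multiplicative for NS, latent-Gaussian for the bounded
#' variants).
#'
#' @param ed The cohort ED `scfc_matrix`.
#' @param subject_jitter Subject weight-jitter SD.
#' @param seed Integer seed (one per subject).
#' @param density,lambda,topo_flip Backbone parameters, used only when
#'   `base` is not supplied.
#' @param base Optional precomputed cohort base (internal reuse).
#' @return Named list of five SC `scfc_matrix` objects.
#' @export
generate_sc <- function(ed, subject_jitter, seed, density = 0.35,
                        lambda = 40, topo_flip = 0.02, base = NULL) {
  if (is.null(base)) base <- make_sc_base(ed, density, lambda, seed)
  set.seed(subseed(seed, 3L))
  m <- length(base$d)
  topo <- base$backbone
  if (topo_flip > 0) {
    flip <- runif(m) < topo_flip * base$p   # flips concentrated where edges are plausible
    topo <- xor(topo, flip)
    topo <- ensure_connected(topo, base$d, base$n)
  }
  jit_ns <- rnorm(m, sd = subject_jitter)
  ns <- rlnorm(m, meanlog = base$ns_meanlog, sdlog = base$ns_sdlog) *
    exp(jit_ns)
  out <- list()
  parc <- ed$parcellation
  mk <- function(vals, variant) {
    vals[!topo] <- 0
    conn_matrix(from_upper_triangle(vals, base$n), "SC", variant, parc)
  }
  out$NS  <- mk(ns, "NS")
  out$NSv <- mk(ns / base$vol_sum, "NSv")
  for (v in c("FA", "iRD", "FRt")) {
    lat <- base$lat[[v]] + rnorm(m, sd = subject_jitter * 2)
    vals <- qbeta(pnorm(lat / sqrt(1 + (subject_jitter * 2)^2)),
                  base$shapes[[v]][1], base$shapes[[v]][2])
    out[[v]] <- mk(vals, v)
  }
  out
}

#' Generate one subject's four functional matrices
#'
#' Applies the ground-truth linear law to the subject's own z-scored,
#' negated SPL/SI/ED predictors (built from the `mapping_source` structural
#' variant), adds per-band Gaussian edge noise, and affinely rescales each
#' band into `[0, 1]`.
#'
#' @param sc_set Named list of the subject's SC matrices.
#' @param ed The ED `scfc_matrix`.
#' @param mapping A [gt_mapping()].
#' @param subject_coeffs Named list per band of realized coefficient vectors
#'   `c(beta0, spl, si, ed)` for this subject (defaults to the mapping means).
#' @param seed Integer seed.
#' @param mapping_source SC variant used for the predictors.
#' @return Named list of four FC `scfc_matrix` objects (bands).
#' @export
generate_fc <- function(sc_set, ed, mapping, subject_coeffs = NULL, seed,
                        mapping_source = "FA") {
  set.seed(subseed(seed, 4L))
  if (is.null(subject_coeffs))
    subject_coeffs <- mapping$coefficients
  pred <- build_predictors(sc_set[[mapping_source]], ed)
  Z <- cbind(spl = -scale(pred$spl)[, 1], si = -scale(pred$si)[, 1],
             ed = -scale(pred$ed)[, 1])
  parc <- ed$parcellation
  out <- list()
  for (b in FC_BANDS) {
    cf <- subject_coeffs[[b]]
    lin <- cf[["beta0"]] + Z %*% cf[c("spl", "si", "ed")]
    lin <- lin + rnorm(length(lin), sd = mapping$noise_sd[[b]])
    rng <- range(lin)
    if (diff(rng) == 0)
      stop_scfc("scfc_degenerate_error", "generated FC is constant in band %s", b)
    vals <- (lin - rng[1]) / diff(rng)
    out[[b]] <- conn_matrix(from_upper_triangle(as.numeric(vals), parc$n),
                            "FC", b, parc)
  }
  out
}

#' Generate a full synthetic cohort
#'
#' Healthy subjects receive coefficients equal to the mapping means plus
#' `Normal(0, individuality_sd)` jitter; patients are generated from the
#' same structural law but with the per-band `patient_shift` added to their
#' coefficients -- divergence is injected only into the SC-to-FC
#' relationship, not the matrices. Patient PANSS scores are integer draws
#' (totals 30-60). The realized per-subject coefficients are stored in
#' `attr(cohort, "ground_truth")`.
#'
#' @param config An [synth_config()].
#' @return An `scfc_cohort` (ED stored once, cohort-wide).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "scfc_synth_config"))
  map <- config$mapping
  geo <- generate_parcellation(config$n_nodes, config$seed)
  base <- make_sc_base(geo$ed, config$sc_density, config$dist_lambda,
                       config$seed)
  jitter_eff <- config$subject_jitter + map$individuality_sd

  n_tot <- config$n_healthy + config$n_patients
  set.seed(subseed(config$seed, 5L))
  ages_h <- runif(config$n_healthy, config$age_healthy[1], config$age_healthy[2])
  ages_p <- runif(config$n_patients, config$age_patient[1], config$age_patient[2])
  panss <- replicate(max(config$n_patients, 1), list(
    positive = sample(7:17, 1), negative = sample(7:17, 1),
    general = sample(16:26, 1)), simplify = FALSE)
  panss <- lapply(panss, function(p) {
    p$total <- p$positive + p$negative + p$general
    p[c("total", "positive", "negative", "general")]
  })
  coef_draws <- rnorm(n_tot * 4 * length(FC_BANDS), sd = map$individuality_sd)

  subjects <- list()
  matrices <- list(ED = geo$ed)
  ground <- list()
  k <- 0
  for (i in seq_len(n_tot)) {
    is_pat <- i > config$n_healthy
    id <- if (is_pat) sprintf("P%02d", i - config$n_healthy)
          else sprintf("H%03d", i)
    subjects[[i]] <- subject(
      id, if (is_pat) ages_p[i - config$n_healthy] else ages_h[i],
      if (is_pat) "psychosis" else "healthy",
      panss = if (is_pat) panss[[i - config$n_healthy]] else NULL)

    coeffs <- list()
    for (b in FC_BANDS) {
      cf <- map$coefficients[[b]]
      cf <- cf + coef_draws[k + seq_along(cf)]
      k <- k + length(cf)
      if (is_pat) {
        shift <- map$patient_shift[[b]]
        if (config$panss_coupling != 0) {
          sev <- (panss[[i - config$n_healthy]]$total - 45) / 15
          shift <- shift * (1 + config$panss_coupling * sev)
        }
        cf <- cf + shift
      }
      coeffs[[b]] <- cf
    }

    sc <- generate_sc(geo$ed, jitter_eff, subseed(config$seed, 100L + 7L * i),
                      density = config$sc_density,
                      lambda = config$dist_lambda,
                      topo_flip = config$topo_flip, base = base)
    fc <- generate_fc(sc, geo$ed, map, coeffs,
                      subseed(config$seed, 100L + 7L * i + 3L),
                      mapping_source = config$mapping_source)
    for (v in names(sc)) matrices[[matrix_key(id, "SC", v)]] <- sc[[v]]
    for (b in names(fc)) matrices[[matrix_key(id, "FC", b)]] <- fc[[b]]
    ground[[id]] <- coeffs
  }
  coh <- cohort(subjects, matrices, geo$parcellation)
  attr(coh, "ground_truth") <- list(
    mapping_source = config$mapping_source,
    noise_sd = as.list(map$noise_sd),
    individuality_sd = map$individuality_sd,
    coefficients = ground)
  coh
}

#' Write / read a cohort directory
#'
#' Lays a cohort out as plain text: `manifest.csv`, `parcellation.csv`
#' (labels + centroids), `ED.csv`, per-subject `<id>_<kind>_<variant>.csv`
#' matrix files, and `ground_truth.json` when the cohort carries realized
#' generator coefficients.
#'
#' @param coh An `scfc_cohort`.
#' @param dir Directory path.
#' @return `write_cohort()`: `dir` invisibly; `read_cohort()`: the cohort.
#' @export
write_cohort <- function(coh, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_manifest(coh$subjects, file.path(dir, "manifest.csv"))
  parc <- coh$parcellation
  pdf_ <- data.frame(label = parc$labels)
  if (!is.null(parc$centroids)) {
    pdf_$x <- parc$centroids[, 1]; pdf_$y <- parc$centroids[, 2]
    pdf_$z <- parc$centroids[, 3]
  }
  utils::write.csv(pdf_, file.path(dir, "parcellation.csv"), row.names = FALSE,
                   quote = FALSE)
  for (nm in names(coh$matrices)) {
    fname <- if (nm == "ED") "ED.csv" else
      paste0(gsub(".", "_", nm, fixed = TRUE), ".csv")
    write_matrix(coh$matrices[[nm]], file.path(dir, fname))
  }
  gt <- attr(coh, "ground_truth")
  if (!is.null(gt))
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  pdf_ <- utils::read.csv(file.path(dir, "parcellation.csv"))
  parc <- parcellation(pdf_$label,
                       centroids = if (all(c("x", "y", "z") %in% names(pdf_)))
                         as.matrix(pdf_[, c("x", "y", "z")]) else NULL)
  subjects <- read_manifest(file.path(dir, "manifest.csv"))
  matrices <- list()
  if (file.exists(file.path(dir, "ED.csv")))
    matrices$ED <- read_matrix(file.path(dir, "ED.csv"), parc, "ED")
  for (f in list.files(dir, pattern = "^.*_(SC|FC|ED)_.*\\.csv$|^.*_ED\\.csv$")) {
    parts <- strsplit(sub("\\.csv$", "", f), "_")[[1]]
    np <- length(parts)
    id <- paste(parts[seq_len(np - 2)], collapse = "_")
    kind <- parts[np - 1]; variant <- parts[np]
    if (variant == "ED" && kind != "SC" && kind != "FC") {
      id <- paste(parts[seq_len(np - 1)], collapse = "_")
      matrices[[matrix_key(id, "ED")]] <-
        read_matrix(file.path(dir, f), parc, "ED")
    } else {
      matrices[[matrix_key(id, kind, variant)]] <-
        read_matrix(file.path(dir, f), parc, kind, variant)
    }
  }
  coh <- cohort(subjects, matrices, parc)
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path))
    attr(coh, "ground_truth") <- jsonlite::read_json(gt_path,
                                                     simplifyVector = TRUE)
  coh
}
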