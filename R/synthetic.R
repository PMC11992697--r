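#' Default synthetic VEP score models
#'
#' Class-conditional Gaussian score models per predictor, on each
#' predictor's native scale, with the panel's thresholds sitting between the
#' class means. `shrinkage` is the disorder separation shrinkage: at
#' disordered positions the pathogenic mean moves toward the benign side by
#' `shrinkage * (mu_pathogenic - mu_benign)` and the benign mean moves
#' further toward the benign side by `benign_shift_frac` of the same amount,
#' so disordered regions show both lower sensitivity and higher specificity
#' while `shrinkage = 0` reduces to a single shared model (an exact null).
#'
#' @param shrinkage Disorder separation shrinkage in `[0, 1)` applied to all
#'   models (default 0.25).
#' @return Named list of model lists (`mode`, `mu_benign`, `mu_pathogenic`,
#'   `sigma`, `threshold`/`direction` or `cut_benign`/`cut_pathogenic`,
#'   `shrinkage`, `benign_shift_frac`, `missing_rate`).
#' @export
default_vep_models <- function(shrinkage = 0.25) {
  tm <- function(mu_b, mu_p, sigma, threshold, direction = "ge",
                 missing_rate = 0.02) {
    list(mode = "threshold", mu_benign = mu_b, mu_pathogenic = mu_p,
         sigma = sigma, threshold = threshold, direction = direction,
         shrinkage = shrinkage, benign_shift_frac = 0.3,
         missing_rate = missing_rate)
  }
  list(
    alphamissense = list(mode = "categorical", mu_benign = 0.28,
                         mu_pathogenic = 0.75, sigma = 0.15,
                         cut_benign = 0.45, cut_pathogenic = 0.55,
                         shrinkage = shrinkage, benign_shift_frac = 0.3,
                         missing_rate = 0.02),
    revel     = tm(0.30, 0.72, 0.15, 0.5),
    vest4     = tm(0.32, 0.74, 0.16, 0.5),
    varity_r  = tm(0.28, 0.70, 0.15, 0.5),
    mvp       = tm(0.50, 0.88, 0.13, 0.7, missing_rate = 0.05),
    esm1b     = tm(-4.5, -10.5, 2.0, -7.5, direction = "lt"),
    polyphen2 = tm(0.35, 0.80, 0.20, 0.5)
  )
}

#' Synthetic cohort configuration
#'
#' Parameters of the generator, defaulting to the statistical structure of
#' the curated clinical cohort the pipeline targets: log-normal protein
#' lengths with median 572 residues, about 30% of residues disordered,
#' 8 variants per protein on average, 85% of variants at disordered
#' positions benign, a 0.85% excess of initiator-methionine variants of
#' which 93% are pathogenic, and VEP scores whose class separation weakens
#' at disordered positions.
#'
#' @param n_proteins Number of proteins.
#' @param length_log_mean,length_log_sd Log-normal length parameters
#'   (median `exp(length_log_mean)`).
#' @param p_idp Probability a protein is fully disordered.
#' @param p_terminus_disordered Probability each terminus starts/ends with a
#'   disordered run.
#' @param p_linker Probability of one internal disordered linker.
#' @param terminal_frac_range,linker_frac_range Uniform ranges for run
#'   lengths as fractions of protein length.
#' @param min_run Minimum latent run length in residues.
#' @param target_disordered_fraction Intended disordered residue fraction
#'   (documentation/validation; the geometry above realises it).
#' @param track_margin Distance of the latent score levels from each tool's
#'   threshold, on 0-1 scales (scaled by 100 for the pLDDT-like channel).
#' @param track_noise_sd Standard deviation of the per-tool AR(1) score
#'   noise on 0-1 scales.
#' @param track_autocorr_length Noise autocorrelation length in residues.
#' @param variants_per_protein_mean Poisson mean of variants per protein.
#' @param p_benign_given_disordered,p_benign_given_ordered Benign label
#'   probabilities by latent state.
#' @param nmet_variant_fraction Target fraction of all variants at the
#'   initiator methionine.
#' @param p_pathogenic_given_nmet Pathogenic probability for start-Met
#'   variants.
#' @param second_met_rate Geometric rate of baseline second-Met distances.
#' @param second_met_shift Extra distance (residues) added for proteins with
#'   pathogenic start-Met variants; 0 makes the two distance distributions
#'   identical in law.
#' @param vep_models Per-VEP score models (see [default_vep_models()]).
#' @param seed Integer root seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_proteins = 1000L,
                             length_log_mean = log(572),
                             length_log_sd = 0.65,
                             p_idp = 0.02,
                             p_terminus_disordered = 0.45,
                             p_linker = 0.5,
                             terminal_frac_range = c(0.10, 0.35),
                             linker_frac_range = c(0.05, 0.30),
                             min_run = 12L,
                             target_disordered_fraction = 0.30,
                             track_margin = 0.25,
                             track_noise_sd = 0.12,
                             track_autocorr_length = 10,
                             variants_per_protein_mean = 8,
                             p_benign_given_disordered = 0.85,
                             p_benign_given_ordered = 0.53,
                             nmet_variant_fraction = 0.0085,
                             p_pathogenic_given_nmet = 0.93,
                             second_met_rate = 0.05,
                             second_met_shift = 20L,
                             vep_models = default_vep_models(),
                             seed = 20260101L) {
  cfg <- as.list(environment())
  probs <- c(p_idp, p_terminus_disordered, p_linker,
             p_benign_given_disordered, p_benign_given_ordered,
             nmet_variant_fraction, p_pathogenic_given_nmet, second_met_rate)
  stopifnot(all(probs >= 0 & probs <= 1), n_proteins >= 1,
            variants_per_protein_mean > 0, second_met_shift >= 0,
            all(vapply(vep_models, function(m) m$shrinkage, 1) < 1))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate synthetic protein sequences
#'
#' Sequences start with M. Each protein is pre-assigned whether it will
#' host a start-Met variant (host probability derived from the configured
#' start-Met variant fraction and the per-protein variant rate) and, if so,
#' the variant's label; hosts with a pathogenic start-Met variant receive a
#' stochastically larger first-to-second-methionine distance
#' (`second_met_shift`). The second methionine is placed exactly at the
#' sampled distance; some proteins have none when the sampled distance
#' exceeds the length.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed (default `cfg$seed`).
#' @return A protein `data.frame` (`protein_id`, `sequence`, `length`) with
#'   extra generator columns `nmet_host` and `nmet_label`.
#' @export
generate_proteins <- function(cfg, seed = cfg$seed) {
  set.seed(as.integer(seed))
  n <- cfg$n_proteins
  len <- pmax(30L, as.integer(round(stats::rlnorm(n, cfg$length_log_mean,
                                                  cfg$length_log_sd))))
  p_host <- min(1, cfg$nmet_variant_fraction * cfg$variants_per_protein_mean /
                  (1 - cfg$nmet_variant_fraction))
  host <- stats::runif(n) < p_host
  nmet_label <- ifelse(host,
                       ifelse(stats::runif(n) < cfg$p_pathogenic_given_nmet,
                              "PATHOGENIC", "BENIGN"),
                       NA_character_)
  d <- 1L + stats::rgeom(n, cfg$second_met_rate)
  d <- d + ifelse(host & nmet_label == "PATHOGENIC" & !is.na(nmet_label),
                  as.integer(cfg$second_met_shift), 0L)
  non_met <- setdiff(.aa_alphabet, "M")
  seqs <- character(n)
  for (i in seq_len(n)) {
    L <- len[i]
    aa <- sample(.aa_alphabet, L, replace = TRUE)
    aa[1L] <- "M"
    stop_forced <- min(d[i], L - 1L)
    if (stop_forced >= 2L) {
      aa[2:stop_forced] <- sample(non_met, stop_forced - 1L, replace = TRUE)
    }
    if (d[i] + 1L <= L) {
      aa[d[i] + 1L] <- "M"
    } else if (L >= 2L) {
      aa[2:L] <- sample(non_met, L - 1L, replace = TRUE)  # no second Met
    }
    seqs[i] <- paste(aa, collapse = "")
  }
  data.frame(protein_id = sprintf("SP%05d", seq_len(n)), sequence = seqs,
             length = len, nmet_host = host, nmet_label = nmet_label,
             stringsAsFactors = FALSE)
}

# latent disorder architecture for one protein: logical vector over residues
.latent_architecture <- function(L, cfg) {
  flags <- rep(FALSE, L)
  if (stats::runif(1) < cfg$p_idp) return(rep(TRUE, L))
  rlen <- function(range) {
    max(cfg$min_run, round(L * stats::runif(1, range[1], range[2])))
  }
  if (stats::runif(1) < cfg$p_terminus_disordered) {
    flags[seq_len(min(L, rlen(cfg$terminal_frac_range)))] <- TRUE
  }
  if (stats::runif(1) < cfg$p_terminus_disordered) {
    k <- min(L, rlen(cfg$terminal_frac_range))
    flags[(L - k + 1L):L] <- TRUE
  }
  if (stats::runif(1) < cfg$p_linker) {
    k <- min(L, rlen(cfg$linker_frac_range))
    # place in the ordered interior with a 5-residue buffer to existing runs
    ord <- which(!flags)
    if (length(ord)) {
      lo <- min(ord) + 5L
      hi <- max(ord) - 5L - k + 1L
      if (hi >= lo) {
        s <- sample(lo:hi, 1L)
        flags[s:(s + k - 1L)] <- TRUE
      }
    }
  }
  flags
}

#' Generate latent disorder architectures and per-tool score tracks
#'
#' A single ground-truth disorder architecture per protein (disordered
#' termini, occasional internal linker, rare fully disordered proteins) is
#' observed through one noisy, autocorrelated score channel per tool, on
#' the tool's native scale and threshold direction (including the inverted
#' pLDDT-like channel). With `track_noise_sd = 0` every tool's thresholded
#' mask equals the latent architecture (away from smoothing transients).
#'
#' @param proteins Output of [generate_proteins()].
#' @param cfg A [synthetic_config()].
#' @param tool_cfgs Disorder tool panel (default [default_tool_configs()]).
#' @param seed Integer seed (default `cfg$seed + 1`).
#' @return A list: `tracks` (named list of track `data.frame`s per tool) and
#'   `latent` (a `data.frame` `protein_id`, `position`, `disordered`).
#' @export
generate_tracks <- function(proteins, cfg,
                            tool_cfgs = default_tool_configs(),
                            seed = cfg$seed + 1L) {
  set.seed(as.integer(seed))
  phi <- exp(-1 / cfg$track_autocorr_length)
  n_tools <- length(tool_cfgs)
  lat_list <- vector("list", nrow(proteins))
  score_list <- lapply(tool_cfgs, function(x) vector("list", nrow(proteins)))
  for (i in seq_len(nrow(proteins))) {
    L <- proteins$length[i]
    lat <- .latent_architecture(L, cfg)
    lat_list[[i]] <- lat
    for (tool in names(tool_cfgs)) {
      tc <- tool_cfgs[[tool]]
      scale <- if (tc$tool_id == "plddt") 100 else 1
      sign <- if (tc$direction == "le") -1 else 1
      level <- tc$threshold + sign * (2 * lat - 1) * cfg$track_margin * scale
      z <- stats::rnorm(L)
      if (L > 1L && phi > 0) {
        e <- as.numeric(stats::filter(z * sqrt(1 - phi^2), phi,
                                      method = "recursive"))
        e[1L] <- z[1L]
      } else {
        e <- z
      }
      s <- level + e * cfg$track_noise_sd * scale
      score_list[[tool]][[i]] <- pmin(scale, pmax(0, s))
    }
  }
  lens <- proteins$length
  pid <- rep(proteins$protein_id, lens)
  pos <- unlist(lapply(lens, seq_len), use.names = FALSE)
  latent <- data.frame(protein_id = pid, position = pos,
                       disordered = unlist(lat_list, use.names = FALSE),
                       stringsAsFactors = FALSE)
  tracks <- lapply(names(tool_cfgs), function(tool) {
    data.frame(protein_id = pid, tool_id = tool, position = pos,
               score = unlist(score_list[[tool]], use.names = FALSE),
               stringsAsFactors = FALSE)
  })
  names(tracks) <- names(tool_cfgs)
  list(tracks = tracks, latent = latent)
}

# effective class means under disorder shrinkage (native scale)
.effective_means <- function(model, disordered) {
  delta <- model$mu_pathogenic - model$mu_benign
  shift <- ifelse(disordered, model$shrinkage, 0)
  list(mu_p = model$mu_pathogenic - shift * delta,
       mu_b = model$mu_benign - model$benign_shift_frac * shift * delta)
}

#' Generate labelled variants with VEP scores
#'
#' Variant positions are uniform over residues 2..L; start-Met hosts add one
#' variant at position 1. Labels are drawn from the benign probability of
#' the latent disorder state at the position. Each VEP's score comes from
#' its class-conditional Gaussian, with disorder-dependent mean shifts (see
#' [default_vep_models()]); categorical predictors cut the underlying score
#' into benign/ambiguous/pathogenic. Scores are independently missing at
#' each VEP's `missing_rate`.
#'
#' @param proteins Output of [generate_proteins()].
#' @param latent Latent architecture table from [generate_tracks()].
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed (default `cfg$seed + 2`).
#' @return A variant `data.frame` in the [read_variants()] layout (with one
#'   column per VEP) plus a generator column `latent_disordered`.
#' @export
generate_variants <- function(proteins, latent, cfg, seed = cfg$seed + 2L) {
  set.seed(as.integer(seed))
  n_var <- stats::rpois(nrow(proteins), cfg$variants_per_protein_mean)
  pid <- rep(proteins$protein_id, n_var)
  L <- rep(proteins$length, n_var)
  pos <- 2L + as.integer(floor(stats::runif(length(pid)) * (L - 1L)))
  hosts <- which(proteins$nmet_host)
  pid <- c(pid, proteins$protein_id[hosts])
  pos <- c(pos, rep(1L, length(hosts)))
  o <- order(match(pid, proteins$protein_id), pos)
  pid <- pid[o]; pos <- pos[o]

  pseq <- stats::setNames(proteins$sequence, proteins$protein_id)
  ref <- substr(pseq[pid], pos, pos)
  alt <- vapply(ref, function(a) sample(setdiff(.aa_alphabet, a), 1L), "")

  lkey <- paste(latent$protein_id, latent$position, sep = "\r")
  dis <- latent$disordered[match(paste(pid, pos, sep = "\r"), lkey)]

  p_benign <- ifelse(dis, cfg$p_benign_given_disordered,
                     cfg$p_benign_given_ordered)
  label <- ifelse(stats::runif(length(pid)) < p_benign, "BENIGN", "PATHOGENIC")
  nmet <- pos == 1L
  nlab <- stats::setNames(proteins$nmet_label, proteins$protein_id)
  label[nmet] <- nlab[pid[nmet]]

  out <- data.frame(protein_id = unname(pid), position = pos,
                    ref_aa = unname(ref), alt_aa = unname(alt), label = label,
                    stringsAsFactors = FALSE)
  patho <- label == "PATHOGENIC"
  for (v in names(cfg$vep_models)) {
    m <- cfg$vep_models[[v]]
    mu <- .effective_means(m, dis)
    mean_vec <- ifelse(patho, mu$mu_p, mu$mu_b)
    s <- stats::rnorm(length(pid), mean_vec, m$sigma)
    if (m$mode == "categorical") {
      cat <- ifelse(s > m$cut_pathogenic, "pathogenic",
                    ifelse(s < m$cut_benign, "benign", "ambiguous"))
      cat[stats::runif(length(pid)) < m$missing_rate] <- NA_character_
      out[[v]] <- cat
    } else {
      s[stats::runif(length(pid)) < m$missing_rate] <- NA_real_
      out[[v]] <- s
    }
  }
  out$latent_disordered <- dis
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic cohort
#'
#' Runs [generate_proteins()], [generate_tracks()] and
#' [generate_variants()] with seeds derived from `cfg$seed`, fully
#' deterministic for a fixed configuration.
#'
#' @param cfg A [synthetic_config()].
#' @param tool_cfgs Disorder tool panel (default [default_tool_configs()]).
#' @return A list: `proteins`, `tracks`, `latent`, `variants`, `config`.
#' @export
generate_cohort <- function(cfg = synthetic_config(),
                            tool_cfgs = default_tool_configs()) {
  proteins <- generate_proteins(cfg, cfg$seed)
  tr <- generate_tracks(proteins, cfg, tool_cfgs, cfg$seed + 1L)
  variants <- generate_variants(proteins, tr$latent, cfg, cfg$seed + 2L)
  list(proteins = proteins, tracks = tr$tracks, latent = tr$latent,
       variants = variants, config = cfg)
}

#' Write a synthetic cohort to disk in the pipeline's input dialects
#'
#' Emits `proteins.fasta`, one `track_<tool>.tsv` per tool, `variants.tsv`
#' and `ground_truth.json` (latent masks and the true generator parameters;
#' consumed only by tests and audits).
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "proteins.fasta")
  writeLines(paste0(">", cohort$proteins$protein_id, "\n",
                    cohort$proteins$sequence), fa)
  for (tool in names(cohort$tracks)) {
    tr <- cohort$tracks[[tool]]
    write_table(tr[, c("protein_id", "position", "score")],
                file.path(dir, paste0("track_", tool, ".tsv")))
  }
  vcols <- setdiff(names(cohort$variants), "latent_disordered")
  write_table(cohort$variants[, vcols], file.path(dir, "variants.tsv"))
  gt <- list(
    config = cohort$config[setdiff(names(cohort$config), "vep_models")],
    vep_models = cohort$config$vep_models,
    latent = cohort$latent
  )
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Closed-form expected sensitivity and specificity of a synthetic VEP
#'
#' For the Gaussian class-conditional score model, the expected confusion
#' rates are available in closed form: for a threshold predictor with
#' pathogenic-if-greater orientation, sensitivity is
#' `P(N(mu_p, sigma) >= t)` and specificity `P(N(mu_b, sigma) < t)` (the
#' orientation flips for low-score-pathogenic predictors); for a
#' categorical predictor the ambiguous band is excluded, so sensitivity is
#' `P(s > cut_p) / (P(s > cut_p) + P(s < cut_b))` under the pathogenic
#' model, and symmetrically for specificity.
#'
#' @param model One element of `cfg$vep_models`.
#' @param disordered Logical; evaluate under the disordered-region means.
#' @return Named numeric vector `c(sensitivity, specificity)`.
#' @export
expected_metrics <- function(model, disordered = FALSE) {
  mu <- .effective_means(model, disordered)
  if (model$mode == "categorical") {
    p_call_p <- function(m) stats::pnorm(model$cut_pathogenic, m, model$sigma,
                                         lower.tail = FALSE)
    p_call_b <- function(m) stats::pnorm(model$cut_benign, m, model$sigma)
    sens <- p_call_p(mu$mu_p) / (p_call_p(mu$mu_p) + p_call_b(mu$mu_p))
    spec <- p_call_b(mu$mu_b) / (p_call_p(mu$mu_b) + p_call_b(mu$mu_b))
  } else if (model$direction == "ge") {
    sens <- stats::pnorm(model$threshold, mu$mu_p, model$sigma,
                         lower.tail = FALSE)
    spec <- stats::pnorm(model$threshold, mu$mu_b, model$sigma)
  } else {
    sens <- stats::pnorm(model$threshold, mu$mu_p, model$sigma)
    spec <- stats::pnorm(model$threshold, mu$mu_b, model$sigma,
                         lower.tail = FALSE)
  }
  c(sensitivity = sens, specificity = spec)
}
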