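#' Default pipeline configuration
#'
#' All analysis constants in one place: window length 22 TR with slide 1,
#' pass band 0.01-0.15 Hz, k-range 2-10 for state selection, alpha 0.05,
#' EDSS percentile cuts 30/70, permutation count, and the synthetic-cohort
#' settings.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    cohort = list(n_hc = 101L, n_mild = 39L, n_nodis = 36L,
                  n_components = 47L, n_timepoints = 255L, TR = 2.25,
                  missingness_rate = 0.08),
    prep = list(enabled = FALSE, despike_c = 4, band = c(0.01, 0.15)),
    window = list(w = 22L, s = 1L, taper = "none"),
    clustering = list(k = NULL, k_range = c(2L, 10L), n_init = 20L,
                      max_points = 2000L),
    stats = list(n_perm = 999L, alpha = 0.05, lower_pct = 30, upper_pct = 70,
                 gate_posthoc = FALSE)
  )
}

merge_config <- function(user, defaults = default_config()) {
  if (is.null(user)) return(defaults)
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- modifyList(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

# polynomial rolling hash of the canonical JSON serialisation of the config
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a cohort's time-courses to TSV files
#'
#' One TSV per participant (rows = TRs, columns = component ids), a cohort
#' manifest TSV, and (when available) a ground-truth state label TSV.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_timecourses <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(sim$timecourses)) {
    write_tsv(as.data.frame(t(sim$timecourses[[id]]$values)),
              file.path(dir, paste0(id, "_timecourses.tsv")))
  }
  manifest <- sim$clinical[, c("participant_id", "group", "subgroup_truth",
                               "age", "sex", "EDSS")]
  manifest$TR <- sim$cohort$TR
  write_tsv(manifest, file.path(dir, "cohort_manifest.tsv"))
  if (!is.null(sim$truth_tr_labels)) {
    truth <- data.frame(
      participant_id = rep(names(sim$truth_tr_labels),
                           each = sim$cohort$n_timepoints),
      TR_index = seq_len(sim$cohort$n_timepoints) - 1L,
      state = unlist(sim$truth_tr_labels, use.names = FALSE))
    write_tsv(truth, file.path(dir, "truth_labels.tsv"))
  }
  invisible(dir)
}

#' Read a cohort of time-course TSVs
#'
#' @param dir Directory written by [write_timecourses()].
#' @return List with `timecourses` (list of [component_timecourses()]) and
#'   `manifest` (data frame).
#' @export
read_timecourses <- function(dir) {
  manifest <- read.delim(file.path(dir, "cohort_manifest.tsv"))
  tcs <- lapply(manifest$participant_id, function(id) {
    m <- as.matrix(read.delim(file.path(dir, paste0(id, "_timecourses.tsv"))))
    component_timecourses(t(m), TR = manifest$TR[1], participant_id = id)
  })
  names(tcs) <- manifest$participant_id
  list(timecourses = tcs, manifest = manifest)
}

#' Validate pipeline inputs
#'
#' Checks shape consistency across participants, TR presence, network
#' assignment coverage, the EDSS grid, and summarises clinical missingness.
#' Failures are reported, not thrown.
#'
#' @param timecourses Named list of [component_timecourses()].
#' @param manifest Cohort manifest data frame (needs `participant_id`; EDSS
#'   checked when present).
#' @param assignment Component-to-network table.
#' @return List with `failures` (character) and `n_checked`.
#' @export
validate_inputs <- function(timecourses, manifest, assignment) {
  failures <- character()
  dims <- vapply(timecourses, function(t) dim(t$values), integer(2))
  if (length(unique(dims[1, ])) > 1) {
    failures <- c(failures, "component counts differ across participants")
  }
  ref_T <- dims[2, 1]
  off <- names(timecourses)[dims[2, ] != ref_T]
  if (length(off)) {
    failures <- c(failures, paste0("participant ", off, " has ",
                                   dims[2, dims[2, ] != ref_T],
                                   " TRs, expected ", ref_T))
  }
  trs <- vapply(timecourses, function(t) t$TR %||% NA_real_, 1)
  if (any(is.na(trs) | trs <= 0)) {
    failures <- c(failures, "missing or non-positive TR")
  }
  n_comp <- dims[1, 1]
  if (nrow(assignment) < n_comp) {
    failures <- c(failures, sprintf(
      "assignment covers %d of %d components", nrow(assignment), n_comp))
  }
  missing_ids <- setdiff(names(timecourses), manifest$participant_id)
  if (length(missing_ids)) {
    failures <- c(failures, paste0("participant ", missing_ids,
                                   " absent from manifest"))
  }
  if ("EDSS" %in% names(manifest)) {
    e <- manifest$EDSS
    bad <- !is.na(e) & !(e >= 0 & e <= 10 & abs(e * 2 - round(e * 2)) < 1e-9)
    if (any(bad)) {
      failures <- c(failures, paste0("EDSS off-grid for ",
                                     manifest$participant_id[bad]))
    }
  }
  list(failures = failures, n_checked = length(timecourses))
}

#' Run the full analysis pipeline
#'
#' Stages: synthesize cohort, (optional) nuisance prep, static FC, windowed
#' FC, state selection/clustering with occupancy re-coding, temporal metrics
#' + ASOC, clinical domain scores + EDSS split, statistics (mass-univariate
#' permutation T-tests with family-wise BH; age-residualised KW + Dunn on
#' metrics and ASOC; age-controlled Spearman partial correlations), and
#' report tables. Any stage failure aborts with the stage name.
#'
#' @param config Path to a YAML/JSON config, or a nested list (merged over
#'   [default_config()]), or `NULL` for defaults.
#' @param seed Overrides the config seed when given.
#' @param outdir Output directory for TSV/JSON artifacts (`NULL`: return
#'   results without writing).
#' @return Invisibly, a list with all stage outputs plus the run manifest.
#' @export
run_pipeline <- function(config = NULL, seed = NULL, outdir = NULL) {
  if (is.character(config)) config <- read_config(config)
  cfg <- merge_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  stage <- "configure"
  result <- tryCatch({
    stage <- "synthesize"
    cohort <- do.call(cohort_config, c(cfg$cohort, list(seed = cfg$seed)))
    assignment <- default_network_assignment(cohort$n_components)
    state_cfg <- state_process_config(
      default_transition_matrix(5L),
      default_state_centroids(assignment), seed = cfg$seed)
    sim <- simulate_cohort(cohort, state_cfg, seed = cfg$seed)
    clinical <- sim$clinical
    tcs <- sim$timecourses

    if (isTRUE(cfg$prep$enabled)) {
      stage <- "prep"
      tcs <- lapply(tcs, prep_timecourses, despike_c = cfg$prep$despike_c,
                    band = cfg$prep$band)
    }

    stage <- "static_fc"
    sfc <- lapply(tcs, static_fc)

    stage <- "windowed_fc"
    if (cfg$window$w > cohort$n_timepoints) {
      stop("window length w = ", cfg$window$w, " exceeds T = ",
           cohort$n_timepoints)
    }
    wfc <- lapply(tcs, sliding_window_fc, w = cfg$window$w, s = cfg$window$s,
                  taper = cfg$window$taper)

    stage <- "states"
    model <- cluster_states(wfc, k = cfg$clustering$k,
                            k_range = seq(cfg$clustering$k_range[1],
                                          cfg$clustering$k_range[2]),
                            n_init = cfg$clustering$n_init,
                            seed = cfg$seed,
                            max_points = cfg$clustering$max_points)

    stage <- "metrics"
    ids <- names(wfc)
    met <- do.call(rbind, lapply(ids, function(id) {
      lab <- model$labels$state[model$labels$participant == id]
      dm <- dynamic_metrics(lab, k = model$k)
      dm$avg_connectivity <- state_average_connectivity(wfc[[id]], lab,
                                                        k = model$k)
      dm$participant_id <- id
      dm
    }))
    medians <- state_medians_cohort(wfc, model)
    modular <- do.call(rbind, lapply(ids, function(id) {
      vapply(seq_len(model$k), function(s) {
        v <- medians[id, s, ]
        if (anyNA(v)) NA_real_ else
          modularity_louvain(v, seed = cfg$seed)$Q
      }, numeric(1))
    }))
    rownames(modular) <- ids
    asoc_tabs <- lapply(wfc, asoc, assignment = assignment)
    asoc_df <- do.call(rbind, lapply(ids, function(id) {
      a <- asoc_tabs[[id]]
      data.frame(participant_id = id, grand = a$grand,
                 setNames(as.data.frame(t(a$intra)),
                          paste0("intra_", names(a$intra))),
                 setNames(as.data.frame(t(a$inter)),
                          paste0("inter_", names(a$inter))),
                 check.names = FALSE)
    }))

    stage <- "clinical"
    test_cols <- default_domain_map()$test
    pat <- clinical$group == "MS"
    domains <- domain_composite(clinical[pat, test_cols])
    split <- edss_split(clinical$EDSS[pat], cfg$stats$lower_pct,
                        cfg$stats$upper_pct)
    groups3 <- rep("HC", nrow(clinical))
    groups3[pat] <- as.character(split$subgroup)

    stage <- "stats"
    alpha <- cfg$stats$alpha
    keep <- groups3 %in% c("HC", "no_disability", "mild_moderate")
    gpairs <- list(c("HC", "no_disability"), c("HC", "mild_moderate"),
                   c("no_disability", "mild_moderate"))
    sfc_mat <- do.call(rbind, sfc)
    static_tests <- do.call(rbind, lapply(gpairs, function(gp) {
      i1 <- groups3 == gp[1]; i2 <- groups3 == gp[2]
      res <- mass_univariate_perm_t(rbind(sfc_mat[i1, , drop = FALSE],
                                          sfc_mat[i2, , drop = FALSE]),
                                    g1 = rep(c(TRUE, FALSE),
                                             c(sum(i1), sum(i2))),
                                    n_perm = cfg$stats$n_perm, seed = cfg$seed)
      data.frame(comparison = paste(gp, collapse = "_vs_"),
                 pair = seq_len(ncol(sfc_mat)), T = res$T_obs,
                 p_uncorrected = res$p,
                 family = paste0("static_", paste(gp, collapse = "_vs_")))
    }))
    static_tests <- apply_family_correction(static_tests)

    dynamic_tests <- do.call(rbind, lapply(seq_len(model$k), function(s) {
      do.call(rbind, lapply(gpairs, function(gp) {
        i1 <- which(groups3 == gp[1] & !is.na(medians[, s, 1]))
        i2 <- which(groups3 == gp[2] & !is.na(medians[, s, 1]))
        if (length(i1) < 2 || length(i2) < 2) return(NULL)
        res <- mass_univariate_perm_t(
          rbind(medians[i1, s, , drop = TRUE],
                medians[i2, s, , drop = TRUE]),
          g1 = rep(c(TRUE, FALSE), c(length(i1), length(i2))),
          n_perm = cfg$stats$n_perm, seed = cfg$seed)
        data.frame(state = s, comparison = paste(gp, collapse = "_vs_"),
                   pair = seq_len(dim(medians)[3]), T = res$T_obs,
                   p_uncorrected = res$p,
                   family = sprintf("dynamic_state%d_%s", s,
                                    paste(gp, collapse = "_vs_")))
      }))
    }))
    dynamic_tests <- apply_family_correction(dynamic_tests)

    metric_tests <- do.call(rbind, lapply(seq_len(model$k), function(s) {
      do.call(rbind, lapply(
        c("fraction_time", "mean_dwell_time", "stickiness",
          "avg_connectivity"), function(mname) {
          v <- met[[mname]][met$state == s]
          pid <- met$participant_id[met$state == s]
          ord <- match(ids, pid)
          vals <- v[ord]
          # a state some group hardly visits cannot be tested for that metric
          n_ok <- table(groups3[keep][!is.na(vals[keep])])
          if (length(n_ok) < 2 || any(n_ok < 2)) return(NULL)
          gt <- metric_group_test(vals[keep], clinical$age[keep],
                                  groups3[keep],
                                  gate_posthoc = cfg$stats$gate_posthoc,
                                  alpha = alpha)
          cbind(data.frame(state = s, metric = mname,
                           kw_chisq = gt$kw$chisq, kw_p = gt$kw$p),
                if (is.null(gt$dunn)) NULL else gt$dunn)
        }))
    }))

    asoc_cols <- setdiff(names(asoc_df), "participant_id")
    asoc_tests <- do.call(rbind, lapply(asoc_cols, function(cl) {
      gt <- metric_group_test(asoc_df[[cl]][keep], clinical$age[keep],
                              groups3[keep],
                              gate_posthoc = cfg$stats$gate_posthoc,
                              alpha = alpha)
      cbind(data.frame(measure = cl, kw_chisq = gt$kw$chisq, kw_p = gt$kw$p),
            if (is.null(gt$dunn)) NULL else gt$dunn)
    }))

    dom_sub <- split$subgroup
    clin_tests <- do.call(rbind, lapply(names(domains), function(d) {
      x <- domains[[d]][dom_sub == "no_disability"]
      y <- domains[[d]][dom_sub == "mild_moderate"]
      pt <- permutation_t_test(x[!is.na(x)], y[!is.na(y)],
                               n_perm = cfg$stats$n_perm, seed = cfg$seed)
      data.frame(domain = d, n_nodis = sum(!is.na(x)),
                 n_mild = sum(!is.na(y)),
                 mean_nodis = mean(x, na.rm = TRUE),
                 mean_mild = mean(y, na.rm = TRUE),
                 T = pt$T, p_uncorrected = pt$p, family = "clinical_domains")
    }))
    clin_tests <- apply_family_correction(clin_tests)

    stage <- "correlations"
    pat_ids <- clinical$participant_id[pat]
    corr_tests <- correlate_fc_clinical(
      medians[pat_ids, , , drop = FALSE], domains, clinical$age[pat])

    stage <- "report"
    manifest <- list(
      config = cfg, config_hash = config_hash(cfg), seed = cfg$seed,
      k = model$k, occupancy = model$occupancy,
      window = cfg$window,
      n_participants = length(ids),
      family_sizes = table(corr_tests$family)[1],
      timestamp = "run")
    list(config = cfg, clinical = clinical, domains = domains,
         edss_split = split, model = model, metrics = met,
         modularity = modular, asoc = asoc_df, medians = medians,
         static_tests = static_tests, dynamic_tests = dynamic_tests,
         metric_tests = metric_tests, asoc_tests = asoc_tests,
         clinical_tests = clin_tests, correlations = corr_tests,
         manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(result$clinical, file.path(outdir, "clinical_raw.tsv"))
    write_tsv(cbind(participant_id =
                      result$clinical$participant_id[result$clinical$group == "MS"],
                    result$domains),
              file.path(outdir, "domain_scores.tsv"))
    write_tsv(result$model$labels, file.path(outdir, "state_labels.tsv"))
    write_tsv(as.data.frame(result$model$centroids),
              file.path(outdir, "state_centroids.tsv"))
    if (!is.null(result$model$selection)) {
      write_tsv(result$model$selection$diagnostics,
                file.path(outdir, "k_selection.tsv"))
    }
    write_tsv(result$metrics, file.path(outdir, "dynamic_metrics.tsv"))
    write_tsv(result$asoc, file.path(outdir, "asoc.tsv"))
    write_tsv(result$static_tests, file.path(outdir, "static_fc_tests.tsv"))
    write_tsv(result$dynamic_tests, file.path(outdir, "dynamic_fc_tests.tsv"))
    write_tsv(result$metric_tests, file.path(outdir, "metric_tests.tsv"))
    write_tsv(result$asoc_tests, file.path(outdir, "asoc_tests.tsv"))
    write_tsv(result$clinical_tests, file.path(outdir, "clinical_tests.tsv"))
    sig <- result$correlations[result$correlations$p_fdr < cfg$stats$alpha, ]
    write_tsv(sig, file.path(outdir, "significant_correlations.tsv"))
    jsonlite::write_json(result$manifest,
                         file.path(outdir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(result)
}
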