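# Study design bookkeeping (condition enumeration, matrix-sentence lists,
# session timing) and orchestration of the full synthetic replication.

#' The closed-set matrix vocabulary (5 categories x 10 words)
#'
#' The standard French matrix-test word set: ten names, verbs, numerals,
#' objects and colours, combined in fixed category order to form five-word
#' sentences.
#'
#' @return data.frame with columns `name`, `verb`, `numeral`, `object`,
#'   `colour`.
#' @export
matrix_vocabulary <- function() {
  data.frame(
    name = c("Agn\u00e8s", "Charlotte", "Emile", "Etienne", "Eug\u00e8ne",
             "F\u00e9lix", "Jean-Luc", "Julien", "Michel", "Sophie"),
    verb = c("ach\u00e8te", "attrape", "demande", "d\u00e9place", "dessine",
             "propose", "ramasse", "ram\u00e8ne", "reprend", "voudrait"),
    numeral = c("deux", "trois", "cinq", "six", "sept",
                "huit", "neuf", "onze", "douze", "quinze"),
    object = c("anneaux", "ballons", "classeurs", "crayons", "jetons",
               "livres", "pions", "piquets", "rubans", "v\u00e9los"),
    colour = c("blancs", "bleus", "bruns", "gris", "jaunes",
               "mauves", "noirs", "roses", "rouges", "verts"))
}

#' Specify the study design
#'
#' Reverberation is applied to the speech only (five RTs), to the noise
#' only, or to both (two extreme RTs each), crossed with two masker
#' modulations and a five-point SNR grid. The near-anechoic reference RT is
#' physically identical across applications and is counted once per
#' modulation.
#'
#' @param applications which reverberation applications are tested.
#' @param rts_speech_only RTs (s) tested with reverberation on the speech.
#' @param rts_other RTs (s) tested for the noise-only and both conditions.
#' @param modulations masker types.
#' @param snr_grid tested SNRs, dB (the study adjusted grids per listener
#'   after a loudness check; the default grid is fixed).
#' @param sentences_per_cell sentences scored per condition x SNR cell.
#' @param words_per_sentence words scored per sentence.
#' @param reference_rt the shared near-anechoic RT label (s).
#' @return list of class `study_design`.
#' @export
study_design <- function(applications = c("speech_only", "noise_only", "both"),
                         rts_speech_only = c(0.15, 0.5, 0.8, 1.1, 1.5),
                         rts_other = c(0.15, 1.5),
                         modulations = c("stationary", "modulated"),
                         snr_grid = c(-16, -12, -8, -4, 0),
                         sentences_per_cell = 10,
                         words_per_sentence = 5,
                         reference_rt = 0.15) {
  applications <- match.arg(applications, several.ok = TRUE)
  if (length(snr_grid) == 0 || length(modulations) == 0)
    stop("empty design grids")
  structure(as.list(environment()), class = "study_design")
}

#' Enumerate the condition x SNR cells of a design
#'
#' Builds all (application, RT, modulation) combinations, collapses the
#' reference-RT duplicates shared across applications (labelled
#' `"reference"`), and crosses the unique combinations with the SNR grid.
#' The default design yields 14 combinations and 70 cells.
#'
#' @param design a [study_design()].
#' @return data.frame with columns `application`, `rt`, `modulation`,
#'   `snr` and `condition` (id string); unique combinations are in
#'   attribute `"combos"`.
#' @export
enumerate_conditions <- function(design = study_design()) {
  stopifnot(inherits(design, "study_design"))
  rows <- do.call(rbind, lapply(design$applications, function(app)
    expand.grid(application = app,
                rt = if (app == "speech_only") design$rts_speech_only
                     else design$rts_other,
                modulation = design$modulations, stringsAsFactors = FALSE)))
  rows$application[rows$rt == design$reference_rt] <- "reference"
  combos <- unique(rows[order(rows$application, rows$rt, rows$modulation), ])
  rownames(combos) <- NULL
  cells <- merge(combos, data.frame(snr = design$snr_grid))
  cells <- cells[order(cells$application, cells$rt, cells$modulation,
                       cells$snr), ]
  rownames(cells) <- NULL
  cells$condition <- sprintf("%s_rt%g_%s_snr%+g", cells$application,
                             cells$rt, cells$modulation, cells$snr)
  structure(cells, combos = combos)
}

#' Build a ten-sentence list using each matrix word exactly once
#'
#' Draws independent permutations of the ten words within each category;
#' sentence i takes the i-th word of each permuted category, in the fixed
#' category order (name, verb, numeral, object, colour). Every one of the
#' 50 words is used exactly once across the list.
#'
#' @param vocab a [matrix_vocabulary()]-shaped data.frame.
#' @param seed RNG seed.
#' @return character vector of 10 sentences.
#' @export
build_sentence_list <- function(vocab = matrix_vocabulary(), seed = 1) {
  if (!is.data.frame(vocab) || nrow(vocab) != 10 || ncol(vocab) != 5 ||
      anyNA(vocab) || length(unique(unlist(vocab))) != 50)
    stop("vocabulary must be 10 x 5 with 50 distinct words")
  with_seed(seed, {
    cols <- lapply(vocab, sample)
    apply(as.data.frame(cols), 1, paste, collapse = " ")
  })
}

#' Estimated session time for a design
#'
#' @param design a [study_design()].
#' @param seconds_per_sentence presentation-plus-response time per sentence
#'   (default 12 s, i.e. about 2 minutes per 10-sentence condition).
#' @return total testing time in minutes.
#' @export
estimate_session_time <- function(design = study_design(),
                                  seconds_per_sentence = 12) {
  if (seconds_per_sentence <= 0) stop("timing constants must be positive")
  cells <- enumerate_conditions(design)
  nrow(cells) * design$sentences_per_cell * seconds_per_sentence / 60
}

# map the shared reference-RT cells into one application's data
subset_application <- function(df, application, reference_rt) {
  out <- df[df$application %in% c(application, "reference"), , drop = FALSE]
  out$application <- application
  out
}

# fit psychometric functions for every listener x condition combination
fit_all <- function(trials, gamma_fixed = 0.1) {
  key <- interaction(trials$listener, trials$application, trials$rt,
                     trials$modulation, drop = TRUE)
  fits <- lapply(split(trials, key), function(d) {
    f <- fit_psychometric(d$snr, d$n_correct, d$n_words,
                          gamma_fixed = gamma_fixed)
    list(listener = d$listener[1], group = d$group[1],
         application = d$application[1], rt = d$rt[1],
         modulation = d$modulation[1], fit = f)
  })
  names(fits) <- NULL
  fits
}

fits_table <- function(fits) {
  do.call(rbind, lapply(fits, function(x) data.frame(
    listener = x$listener, group = x$group, application = x$application,
    rt = x$rt, modulation = x$modulation, m = x$fit$m, w = x$fit$w,
    gamma = x$fit$gamma, lambda = x$fit$lambda,
    converged = x$fit$converged)))
}

# long-format RAU scores at one SNR for the ANOVA battery
rau_scores_at <- function(fits, snr) {
  do.call(rbind, lapply(fits, function(x) data.frame(
    listener = x$listener, group = x$group, application = x$application,
    rt = factor(x$rt), noise = x$modulation,
    score = rau(predict.psychometric_fit(x$fit, snr)))))
}

#' Run the full synthetic replication
#'
#' Generates a cohort, simulates word-scoring trials over the whole design,
#' fits all psychometric functions, selects per-application optimal SNRs
#' (fewest floor/ceiling cases) and per-group benefit-maximizing SNRs, and
#' runs the hypothesis battery: group-by-RT interactions for the
#' speech-only and both-sources conditions, the three-way
#' group-by-RT-by-noise interaction for the noise-only condition, per-group
#' RT-by-noise interactions, and the paired t-test contrasts against the
#' reference RT. Dip-listening benefits are always reported at both the
#' optimal and the benefit-maximizing SNR.
#'
#' @param n_per_group listeners per group.
#' @param seed master seed; cohort, trials and analyses derive sub-seeds
#'   from it.
#' @param config an [effect_config()].
#' @param design a [study_design()].
#' @param bf_method `"laplace"` (default) or `"bic"` for the ANOVA Bayes
#'   factors.
#' @param out_dir optional directory: writes `trials.csv`, `fits.csv` and
#'   `report.json`.
#' @return list of class `replication_report`.
#' @export
run_replication <- function(n_per_group = 32, seed = 1,
                            config = effect_config(),
                            design = study_design(),
                            bf_method = c("laplace", "bic"),
                            out_dir = NULL) {
  bf_method <- match.arg(bf_method)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  cohort <- stage("cohort",
                  generate_cohort(n_per_group, seed = seed, config = config,
                                  design = design))
  trials <- stage("trials", simulate_trials(cohort, design, seed = seed + 1))
  fits <- stage("fits", fit_all(trials))
  ftab <- fits_table(fits)
  grid <- design$snr_grid
  apps <- c("speech_only", "noise_only", "both")

  # per-application optimal SNR over both groups' fits
  opt_snr <- stage("optimal_snr", {
    sapply(apps, function(a) {
      fa <- Filter(function(x) x$application %in% c(a, "reference"), fits)
      as.numeric(optimal_snr(lapply(fa, `[[`, "fit"), grid))
    })
  })

  # benefit-maximizing SNR per group: mean dip benefit at the reference RT
  dip_max_snr <- stage("dip_max_snr", {
    ref <- Filter(function(x) x$application == "reference", fits)
    sapply(c("NH", "HI"), function(g) {
      fg <- Filter(function(x) x$group == g, ref)
      by_l <- split(fg, vapply(fg, `[[`, character(1), "listener"))
      ben <- sapply(grid, function(s) mean(vapply(by_l, function(fl) {
        mods <- vapply(fl, `[[`, character(1), "modulation")
        dip_benefit(fl[[which(mods == "modulated")]]$fit,
                    fl[[which(mods == "stationary")]]$fit, s)
      }, numeric(1))))
      grid[which.max(ben)]
    })
  })

  anova_at <- function(app, snr, target, groups = c("NH", "HI")) {
    df <- rau_scores_at(Filter(function(x)
      x$application %in% c(app, "reference") & x$group %in% groups, fits), snr)
    df$application <- app
    facs <- if (length(groups) > 1) c("group", "rt", "noise")
            else c("rt", "noise")
    bf <- mixed_anova_bf(df, target, score = "score", subject = "listener",
                         factors = facs, method = bf_method)
    list(application = app, snr = snr, target = target,
         bf10 = bf$bf10, category = classify_evidence(bf$bf10),
         method = bf$method)
  }

  hypotheses <- stage("hypotheses", {
    h <- list()
    h$H1 <- anova_at("speech_only", opt_snr[["speech_only"]], "rt:group")
    h$H2 <- anova_at("noise_only", opt_snr[["noise_only"]], "rt:noise:group")
    h$H2_dipmax <- anova_at("noise_only", dip_max_snr[["HI"]],
                            "rt:noise:group")
    h$H3_1 <- anova_at("both", opt_snr[["both"]], "rt:group")
    h$H3_1_dipmax <- anova_at("both", dip_max_snr[["HI"]], "rt:group")
    h$H3_2_a <- anova_at("both", opt_snr[["both"]], "rt:noise", groups = "NH")
    h$H3_2_a_dipmax <- anova_at("both", dip_max_snr[["NH"]], "rt:noise",
                                groups = "NH")
    h$H3_2_b <- anova_at("both", opt_snr[["both"]], "rt:noise", groups = "HI")
    h$H3_2_b_dipmax <- anova_at("both", dip_max_snr[["HI"]], "rt:noise",
                                groups = "HI")
    # H1-1: paired contrasts reference vs each higher RT (speech only)
    sp <- rau_scores_at(Filter(function(x)
      x$application %in% c("speech_only", "reference"), fits),
      opt_snr[["speech_only"]])
    rts <- sort(unique(as.numeric(as.character(sp$rt))))
    ref_rt <- min(rts)
    h$H1_1 <- list()
    for (g in c("NH", "HI")) for (r in setdiff(rts, ref_rt)) {
      dg <- sp[sp$group == g & sp$noise == "stationary", ]
      dd <- merge(dg[as.numeric(as.character(dg$rt)) == ref_rt,
                     c("listener", "score")],
                  dg[as.numeric(as.character(dg$rt)) == r,
                     c("listener", "score")], by = "listener")
      bf <- jzs_paired_bf(dd$score.x - dd$score.y)
      h$H1_1[[sprintf("%s_rt%g", g, r)]] <-
        list(bf10 = bf$bf10, category = classify_evidence(bf$bf10))
    }
    # H1-2: group comparison of the reference-vs-max-RT score drop
    drops <- lapply(c("NH", "HI"), function(g) {
      dg <- sp[sp$group == g & sp$noise == "stationary", ]
      dd <- merge(dg[as.numeric(as.character(dg$rt)) == ref_rt,
                     c("listener", "score")],
                  dg[as.numeric(as.character(dg$rt)) == max(rts),
                     c("listener", "score")], by = "listener")
      dd$score.x - dd$score.y
    })
    bf12 <- jzs_two_sample_bf(drops[[1]], drops[[2]])
    h$H1_2 <- list(bf10 = bf12$bf10, category = classify_evidence(bf12$bf10))
    h
  })

  # dip benefit per group at the two analysis SNRs, in the noise-only
  # condition at each masker RT
  dip_summary <- stage("dip_benefit", {
    out <- list()
    for (g in c("NH", "HI")) {
      for (lab in c("optimal", "dip_max")) {
        s <- if (lab == "optimal") opt_snr[["noise_only"]]
             else dip_max_snr[[g]]
        fg <- Filter(function(x)
          x$application %in% c("noise_only", "reference") & x$group == g, fits)
        for (r in sort(unique(vapply(fg, `[[`, numeric(1), "rt")))) {
          fr <- Filter(function(x) x$rt == r, fg)
          by_l <- split(fr, vapply(fr, `[[`, character(1), "listener"))
          ben <- vapply(by_l, function(fl) {
            mods <- vapply(fl, `[[`, character(1), "modulation")
            dip_benefit(fl[[which(mods == "modulated")]]$fit,
                        fl[[which(mods == "stationary")]]$fit, s)
          }, numeric(1))
          out[[sprintf("%s_%s_rt%g", g, lab, r)]] <-
            list(group = g, snr = s, rt = r, mean_benefit_rau = mean(ben))
        }
      }
    }
    out
  })

  # floor/ceiling bookkeeping: share of individual predicted scores
  # inside [15%, 95%] per application at its analysis SNR
  inside <- stage("floor_ceiling", {
    sapply(apps, function(a) {
      fa <- Filter(function(x) x$application %in% c(a, "reference"), fits)
      p <- vapply(fa, function(x)
        predict.psychometric_fit(x$fit, opt_snr[[a]]), numeric(1))
      mean(p > 0.15 & p < 0.95)
    })
  })

  cells <- enumerate_conditions(design)
  report <- structure(list(
    seed = seed, n_per_group = n_per_group,
    n_combos = nrow(attr(cells, "combos")), n_cells = nrow(cells),
    session_minutes = estimate_session_time(design),
    optimal_snr = as.list(opt_snr), dip_max_snr = as.list(dip_max_snr),
    pct_within_bounds = as.list(inside),
    hypotheses = hypotheses, dip_benefit = dip_summary,
    fits = ftab, trials = trials, bf_method = bf_method),
    class = "replication_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(trials, file.path(out_dir, "trials.csv"),
                     row.names = FALSE)
    utils::write.csv(ftab, file.path(out_dir, "fits.csv"), row.names = FALSE)
    slim <- report[setdiff(names(report), c("fits", "trials"))]
    jsonlite::write_json(slim, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @exportS3Method base::print
print.replication_report <- function(x, ...) {
  cat(sprintf("synthetic replication: %d listeners/group, %d combos, %d cells\n",
              x$n_per_group, x$n_combos, x$n_cells))
  cat(sprintf("optimal SNRs: speech %g, noise %g, both %g dB; dip-max NH %g, HI %g dB\n",
              x$optimal_snr$speech_only, x$optimal_snr$noise_only,
              x$optimal_snr$both, x$dip_max_snr$NH, x$dip_max_snr$HI))
  for (h in c("H1", "H2", "H2_dipmax", "H3_1", "H3_1_dipmax",
              "H3_2_a", "H3_2_b")) {
    hy <- x$hypotheses[[h]]
    cat(sprintf("  %-12s BF10 = %-10.4g (%s) at %g dB\n", h, hy$bf10,
                hy$category, hy$snr))
  }
  invisible(x)
}

#' Plot group-mean psychometric curves in RAU
#'
#' RAU conversion of the parameter-averaged group curves against SNR, one
#' panel per group, line style by RT, colour by masker type.
#'
#' @param report a [run_replication()] result (or a fits table).
#' @param application which reverberation application to plot.
#' @return invisibly, the plotted curve data.
#' @export
plot_group_curves <- function(report, application = "speech_only") {
  ftab <- if (inherits(report, "replication_report")) report$fits else report
  ftab <- ftab[ftab$application %in% c(application, "reference") &
               ftab$converged, ]
  snr <- seq(-20, 4, 0.25)
  rts <- sort(unique(ftab$rt))
  groups <- unique(ftab$group)
  oldpar <- graphics::par(mfrow = c(1, length(groups)))
  on.exit(graphics::par(oldpar))
  out <- list()
  for (g in groups) {
    graphics::plot(NULL, xlim = range(snr), ylim = c(-23, 123),
                   xlab = "SNR (dB)", ylab = "score (RAU)",
                   main = paste(g, "-", application))
    for (i in seq_along(rts)) for (mod in unique(ftab$modulation)) {
      sub <- ftab[ftab$rt == rts[i] & ftab$modulation == mod, ]
      if (nrow(sub) == 0) next
      y <- rau(psychometric(snr, mean(sub$m), mean(sub$w),
                            mean(sub$gamma), mean(sub$lambda)))
      graphics::lines(snr, y, lty = i,
                      col = if (mod == "modulated") "tomato3" else "grey20")
      out[[paste(g, rts[i], mod)]] <- data.frame(group = g, rt = rts[i],
                                                 modulation = mod,
                                                 snr = snr, rau = y)
    }
    graphics::legend("topleft", bty = "n", cex = 0.7,
                     legend = c(paste("RT", rts, "s"),
                                "stationary", "modulated"),
                     lty = c(seq_along(rts), 1, 1),
                     col = c(rep("grey20", length(rts)), "grey20", "tomato3"))
  }
  invisible(do.call(rbind, out))
}
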