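#' Render a synthetic brightfield IHC image with planted ground truth
#'
#' Forward Beer-Lambert model of a hematoxylin-counterstained DAB slide:
#' each pixel's RGB intensity is `255 * 10^-(OD_hem * v_hem + OD_dab * v_dab)`
#' channel-wise with the unit stain vectors of `model`, plus optional
#' additive Gaussian intensity noise (clipped to [0, 255]). Planted objects
#' are disks, ellipses, or thin fibers of known size and DAB optical
#' density; pairs of objects may be fused by declared bridges to exercise
#' declustering. Undeclared overlaps are an error because they would make
#' the ground truth ambiguous.
#'
#' @param width_px,height_px Canvas size in pixels.
#' @param pixel_size_um Pixel size (default 0.5 um, a 20x scan).
#' @param background_hematoxylin_od Uniform hematoxylin OD of the
#'   background tissue (default 0.3).
#' @param noise_sd SD of additive Gaussian intensity noise, in 0-255 units
#'   (default 2, approximating scanner shot noise).
#' @param objects Data frame of planted objects with columns `x`, `y`
#'   (center, 0-based pixel coordinates), `shape` (`"disk"`, `"ellipse"`,
#'   `"fiber"`), `area_um2`, `dab_od`, and optionally `axis_ratio`
#'   (ellipse minor/major, default 1/3), `angle` (radians, default 0),
#'   `fiber_width_um` (default 1.5).
#' @param bridges Optional data frame fusing object pairs: columns `from`,
#'   `to` (row indices into `objects`) and `dab_od` of the bridge;
#'   `width_um` optional (default 1.5).
#' @param model A [stain_model()].
#' @param seed Integer seed (mandatory: generators are pure functions of
#'   their parameters and seed).
#' @return List with `image` (an [rgb_image()]) and `truth` (tibble of
#'   planted objects: `object_id`, `shape`, `x`, `y`, nominal `area_um2`,
#'   rasterized `rasterized_area_um2`, `dab_od`).
#' @export
render_ihc_image <- function(width_px = 400, height_px = 400,
                             pixel_size_um = 0.5,
                             background_hematoxylin_od = 0.3,
                             noise_sd = 2,
                             objects = NULL,
                             bridges = NULL,
                             model = stain_model(),
                             seed = 1) {
  if (is.null(seed)) abort("`seed` is mandatory for reproducibility.")
  ps <- pixel_size_um
  h <- height_px; w <- width_px
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)
  od_dab <- matrix(0, h, w)
  masks <- list()
  truth <- .empty_truth()
  if (!is.null(objects) && nrow(objects) > 0L) {
    objects <- as_tibble(objects)
    for (i in seq_len(nrow(objects))) {
      ob <- objects[i, ]
      m <- .rasterize_object(ob, xs, ys, ps)
      if (!any(m)) abort(sprintf("Planted object %d rasterizes to no pixels.", i))
      if (any(xs[m] < 0 | xs[m] > w - 1 | ys[m] < 0 | ys[m] > h - 1)) {
        abort(sprintf("Planted object %d extends outside the canvas.", i))
      }
      masks[[i]] <- m
      truth <- bind_rows(truth, tibble(
        object_id = i, shape = ob$shape, x = ob$x, y = ob$y,
        area_um2 = ob$area_um2,
        rasterized_area_um2 = sum(m) * ps^2,
        dab_od = ob$dab_od))
    }
    declared <- if (is.null(bridges)) character(0) else {
      paste(pmin(bridges$from, bridges$to), pmax(bridges$from, bridges$to))
    }
    if (length(masks) > 1L) {
      for (i in seq_len(length(masks) - 1L)) {
        for (j in (i + 1L):length(masks)) {
          if (any(masks[[i]] & masks[[j]]) &&
              !(paste(i, j) %in% declared)) {
            abort(sprintf(
              "Planted objects %d and %d overlap without a declared bridge.", i, j))
          }
        }
      }
    }
    for (i in seq_along(masks)) {
      od_dab[masks[[i]]] <- pmax(od_dab[masks[[i]]], objects$dab_od[i])
    }
  }
  if (!is.null(bridges) && nrow(bridges) > 0L) {
    for (k in seq_len(nrow(bridges))) {
      br <- bridges[k, ]
      wd <- if ("width_um" %in% names(br)) br$width_um else 1.5
      a <- objects[br$from, ]; b <- objects[br$to, ]
      m <- .rasterize_segment(a$x, a$y, b$x, b$y, wd / ps, xs, ys)
      od_dab[m] <- pmax(od_dab[m], br$dab_od)
    }
  }
  v <- model$vectors
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    od_ch <- background_hematoxylin_od * v["hematoxylin", ch] +
      od_dab * v["dab", ch]
    img[, , ch] <- 255 * 10^(-od_ch)
  }
  if (noise_sd > 0) {
    img <- withr::with_seed(seed, img + rnorm(length(img), sd = noise_sd))
    img <- pmin(pmax(img, 0), 255)
  }
  list(image = rgb_image(img, pixel_size_um = ps), truth = truth)
}

.empty_truth <- function() {
  tibble(object_id = integer(), shape = character(), x = numeric(),
         y = numeric(), area_um2 = numeric(), rasterized_area_um2 = numeric(),
         dab_od = numeric())
}

.rasterize_object <- function(ob, xs, ys, ps) {
  shape <- ob$shape
  if (shape == "disk") {
    r <- sqrt(ob$area_um2 / pi) / ps
    (xs - ob$x)^2 + (ys - ob$y)^2 <= r^2
  } else if (shape == "ellipse") {
    q <- if ("axis_ratio" %in% names(ob) && !is.na(ob$axis_ratio)) ob$axis_ratio else 1 / 3
    th <- if ("angle" %in% names(ob) && !is.na(ob$angle)) ob$angle else 0
    a <- sqrt(ob$area_um2 / (pi * q)) / ps   # semi-major in px
    b <- a * q
    u <- (xs - ob$x) * cos(th) + (ys - ob$y) * sin(th)
    vv <- -(xs - ob$x) * sin(th) + (ys - ob$y) * cos(th)
    (u / a)^2 + (vv / b)^2 <= 1
  } else if (shape == "fiber") {
    wd <- if ("fiber_width_um" %in% names(ob) && !is.na(ob$fiber_width_um)) ob$fiber_width_um else 1.5
    len <- ob$area_um2 / wd                   # um
    th <- if ("angle" %in% names(ob) && !is.na(ob$angle)) ob$angle else 0
    dx <- cos(th) * len / 2 / ps
    dy <- sin(th) * len / 2 / ps
    .rasterize_segment(ob$x - dx, ob$y - dy, ob$x + dx, ob$y + dy,
                       wd / ps, xs, ys)
  } else {
    abort(sprintf("Unknown planted shape '%s'.", shape))
  }
}

# Pixels within width/2 of the segment (x0,y0)-(x1,y1); all in pixel units.
.rasterize_segment <- function(x0, y0, x1, y1, width_px, xs, ys) {
  vx <- x1 - x0; vy <- y1 - y0
  L2 <- vx^2 + vy^2
  t <- if (L2 == 0) 0 else pmin(pmax(((xs - x0) * vx + (ys - y0) * vy) / L2, 0), 1)
  d2 <- (xs - (x0 + t * vx))^2 + (ys - (y0 + t * vy))^2
  d2 <= (width_px / 2)^2
}

#' Simulate an aging autopsy cohort with planted group structure
#'
#' Generates a case table, a long-format CASI table, and a planted-label
#' table. Planted resistant cases satisfy the resistant predicate by
#' construction (non-demented, CASI within two years of death, Braak <=
#' III, CERAD none, age >= 85); planted resilient cases satisfy the
#' resilient predicate (non-demented, recent CASI, Braak VI, CERAD
#' frequent); the dementia pool satisfies the matching pool criteria
#' (demented, Braak VI, CERAD frequent). Decoy cases violating exactly one
#' selection criterion each stress the classifiers, and background cases
#' are constructed to satisfy neither predicate. Group-level pathology
#' shifts follow the study's direction of effect: the dementia pool
#' carries LATE-NC at high prevalence (vs. low in resistant cases), more
#' cortical pTau/pTDP-43 burden, higher vascular scores and lower brain
#' weight. Non-demented CASI trajectories are stable; demented ones
#' decline linearly through the referral threshold of 85 and are censored
#' at diagnosis.
#'
#' @param n_cases Total cohort size (default 684 autopsies).
#' @param n_resistant,n_resilient Planted index-group sizes (defaults 14
#'   and 7).
#' @param n_pool Planted dementia-pool size (default 60).
#' @param late_prevalence_pool,late_prevalence_resistant Probability of any
#'   LATE-NC in the dementia pool and the resistant group (defaults 13/14
#'   and 2/14).
#' @param seed Integer seed (mandatory).
#' @return List of tibbles: `cohort` (one row per case), `casi`
#'   (`case_id`, `date`, `casi`), `labels` (`case_id`, `planted_group`).
#' @export
simulate_cohort <- function(n_cases = 684, n_resistant = 14, n_resilient = 7,
                            n_pool = 60,
                            late_prevalence_pool = 13 / 14,
                            late_prevalence_resistant = 2 / 14,
                            seed = 1) {
  if (is.null(seed)) abort("`seed` is mandatory for reproducibility.")
  n_decoy <- 9L
  n_bg <- n_cases - n_resistant - n_resilient - n_pool - n_decoy
  if (n_bg < 0) abort("Planted group sizes exceed `n_cases`.")
  withr::with_seed(seed, {
    groups <- c(rep("resistant", n_resistant), rep("resilient", n_resilient),
                rep("ad_pool", n_pool),
                paste0("decoy_", c("age", "braak", "cerad", "latency",
                                   "dementia", "res_braak", "res_cerad",
                                   "res_latency", "res_dementia")),
                rep("background", n_bg))
    n <- length(groups)
    id <- sprintf("C%04d", seq_len(n))
    is_res <- groups == "resistant"
    is_ril <- groups == "resilient"
    is_pool <- groups == "ad_pool"
    is_bg <- groups == "background"

    sex <- sample(c("F", "M"), n, replace = TRUE)
    # fix planted sex splits so same-sex matching is well exercised
    sex[is_res] <- rep(c("F", "M"), length.out = n_resistant)
    sex[is_ril] <- rep(c("F", "F", "M", "F", "M", "F", "F"),
                       length.out = n_resilient)
    sex[is_pool] <- rep(c("F", "M"), length.out = n_pool)

    age <- round(runif(n, 70, 100), 1)
    age[is_res] <- round(runif(n_resistant, 85, 100), 1)   # >= 85 by design
    age[is_ril] <- round(runif(n_resilient, 78, 95), 1)
    age[is_pool] <- round(runif(n_pool, 78, 100), 1)
    year <- sample(1996:2018, n, replace = TRUE)
    death_date <- as.Date(paste0(year, "-01-01")) +
      sample.int(364, n, replace = TRUE)
    pmi <- round(runif(n, 2, 48), 1)

    dementia <- rep(FALSE, n)
    dementia[is_pool] <- TRUE
    dementia[groups %in% c("decoy_dementia", "decoy_res_dementia")] <- TRUE
    dementia[is_bg] <- runif(n_bg) < 0.35

    braak <- integer(n)
    cerad <- integer(n)
    braak[is_res] <- sample(0:3, n_resistant, replace = TRUE)
    cerad[is_res] <- 0L
    braak[is_ril] <- 6L; cerad[is_ril] <- 3L
    braak[is_pool] <- 6L; cerad[is_pool] <- 3L
    # background: never resistant (CERAD >= 1 whenever Braak <= III) and
    # never resilient/pool-grade (no Braak VI + CERAD frequent combination)
    bg_braak <- sample(1:6, n_bg, replace = TRUE)
    bg_cerad <- ifelse(bg_braak <= 3, sample(1:3, n_bg, replace = TRUE),
                       sample(0:2, n_bg, replace = TRUE))
    braak[is_bg] <- bg_braak
    cerad[is_bg] <- bg_cerad
    # decoys: one violated criterion each, otherwise index-grade
    dec <- function(g) which(groups == g)
    braak[dec("decoy_age")] <- 2L;    cerad[dec("decoy_age")] <- 0L
    age[dec("decoy_age")] <- 80
    braak[dec("decoy_braak")] <- 4L;  cerad[dec("decoy_braak")] <- 0L
    age[dec("decoy_braak")] <- 90
    braak[dec("decoy_cerad")] <- 2L;  cerad[dec("decoy_cerad")] <- 1L
    age[dec("decoy_cerad")] <- 90
    braak[dec("decoy_latency")] <- 1L; cerad[dec("decoy_latency")] <- 0L
    age[dec("decoy_latency")] <- 92
    braak[dec("decoy_dementia")] <- 1L; cerad[dec("decoy_dementia")] <- 0L
    age[dec("decoy_dementia")] <- 91
    braak[dec("decoy_res_braak")] <- 5L;  cerad[dec("decoy_res_braak")] <- 3L
    braak[dec("decoy_res_cerad")] <- 6L;  cerad[dec("decoy_res_cerad")] <- 2L
    braak[dec("decoy_res_latency")] <- 6L; cerad[dec("decoy_res_latency")] <- 3L
    braak[dec("decoy_res_dementia")] <- 6L; cerad[dec("decoy_res_dementia")] <- 3L

    long_latency <- groups %in% c("decoy_latency", "decoy_res_latency")

    late_p <- ifelse(is_pool | dementia, late_prevalence_pool,
                     ifelse(is_res, late_prevalence_resistant, 0.1))
    has_late <- runif(n) < late_p
    late_stage <- ifelse(has_late,
                         sample(c("amygdala", "hippocampal", "neocortical"),
                                n, replace = TRUE,
                                prob = c(0.3, 0.4, 0.3)),
                         "none")
    lbd <- sample(c("none", "brainstem", "limbic-amygdala", "neocortical"),
                  n, replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1))

    vasc_shift <- ifelse(dementia, 1L, 0L)
    cohort <- tibble(
      case_id = id, sex = sex, age_at_death = age, year_of_death = year,
      death_date = death_date, pmi_hours = pmi,
      dementia_status = dementia,
      braak_stage = braak, cerad_score = cerad,
      thal_phase = pmin(5L, cerad + sample(0:2, n, replace = TRUE)),
      lbd_distribution = lbd, late_nc_stage = late_stage,
      late_nc_present = as.integer(late_stage != "none"),
      n_microinfarcts = stats::rpois(n, 0.8 + 0.6 * vasc_shift),
      n_macroinfarcts = stats::rpois(n, 0.3 + 0.4 * vasc_shift),
      caa_severity = pmin(3L, stats::rpois(n, 0.5 + 0.8 * vasc_shift)),
      arteriolosclerosis = pmin(3L, 1L + stats::rpois(n, 0.6 + 0.5 * vasc_shift)),
      atherosclerosis = pmin(3L, 1L + stats::rpois(n, 0.6 + 0.3 * vasc_shift)),
      brain_weight_g = round(rnorm(n, 1230 - 110 * vasc_shift, 80)),
      apoe_genotype = sample(c("e3/e3", "e3/e4", "e2/e3", "e4/e4"), n,
                             replace = TRUE, prob = c(0.6, 0.25, 0.1, 0.05)),
      education_years = pmax(6, round(rnorm(n, 14, 3))),
      ptau_mfg_score = pmin(3L, stats::rpois(n, ifelse(dementia, 2.2, 0.6))),
      ptdp_hippocampus_score = ifelse(has_late,
                                      pmin(6L, 1L + stats::rpois(n, 2)), 0L)
    )

    casi <- .simulate_casi(cohort, long_latency)
    list(cohort = cohort,
         casi = casi,
         labels = tibble(case_id = id, planted_group = groups))
  })
}

# Biennial CASI visits. Non-demented: stable high scores with the last
# visit inside the two-year window (except planted long-latency decoys).
# Demented: linear decline crossing the referral threshold (85), censored
# at diagnosis years before death.
.simulate_casi <- function(cohort, long_latency) {
  n <- nrow(cohort)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    dd <- cohort$death_date[i]
    if (cohort$dementia_status[i]) {
      gap_last <- runif(1, 3, 9)                # censored years before death
      n_vis <- sample(3:6, 1)
      offs <- gap_last + 2 * (rev(seq_len(n_vis)) - 1)
      scores <- round(96 - seq(0, 14, length.out = n_vis) + rnorm(n_vis, 0, 1))
      scores[n_vis] <- min(scores[n_vis], 84)   # final visit triggers referral
    } else {
      gap_last <- if (long_latency[i]) runif(1, 2.2, 3.5) else runif(1, 0.2, 1.8)
      n_vis <- sample(3:6, 1)
      offs <- gap_last + 2 * (rev(seq_len(n_vis)) - 1)
      scores <- round(pmin(100, pmax(86, rnorm(n_vis, 94, 2.5))))
    }
    rows[[i]] <- tibble(case_id = cohort$case_id[i],
                        date = dd - round(offs * 365.25),
                        casi = pmax(0, pmin(100, scores)))
  }
  bind_rows(rows)
}

#' Simulate progeny genotype counts from a transgene cross
#'
#' Multinomial draw of `n` progeny from the model's post-selection expected
#' proportions.
#'
#' @param model A [cross_model()].
#' @param n Number of scored progeny (e.g. 561 or 563).
#' @param seed Integer seed (mandatory).
#' @return Named integer vector of counts per genotype class.
#' @export
simulate_progeny <- function(model = cross_model(), n, seed) {
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory.")
  if (n <= 0) abort("`n` must be positive.")
  p <- expected_proportions(model)
  counts <- withr::with_seed(seed, as.integer(rmultinom(1, n, p)))
  setNames(counts, names(p))
}
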