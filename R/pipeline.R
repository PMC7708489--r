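# End-to-end pipeline: simulate -> high-pass -> (rank estimate) -> NMF ->
# select -> phase retrieval -> focusing/validation -> memory-effect imaging,
# with a run manifest and optional on-disk artifacts.

#' Default pipeline configuration
#'
#' Nested list consumed by [run_pipeline()]. Any field can be overridden by
#' passing a partial list; unknown fields are rejected.
#'
#' @param n_targets,n_slm,grid,n_patterns,me_range,speckle_grain,excitation_exponent,photon_budget,read_noise_sd
#'   forwarded to [simulation_config()].
#' @param seed master seed.
#' @param rank NMF rank (NULL: estimated with [estimate_rank()] up to
#'   `rank_max` then doubled as the recommended overestimate).
#' @param rank_max cap for rank estimation.
#' @param highpass_sigma background-removal width in pixels.
#' @param n_restarts,n_iter_max,nmf_tol NMF settings.
#' @param theta_dup,theta_var selection thresholds.
#' @param pr_iter,pr_tol phase-retrieval settings.
#' @param theta_focus epi-variance verdict threshold.
#' @param theta_edge displacement-graph edge threshold.
#' @return named list.
#' @export
pipeline_config <- function(n_targets = 10, n_slm = 64, grid = c(48, 48),
                            n_patterns = 1024, me_range = 12,
                            speckle_grain = 2, excitation_exponent = 1,
                            photon_budget = Inf, read_noise_sd = 0,
                            seed = 1L, rank = NULL, rank_max = 12,
                            highpass_sigma = 6, n_restarts = 2,
                            n_iter_max = 300, nmf_tol = 1e-6,
                            theta_dup = 0.8, theta_var = 2,
                            pr_iter = 150, pr_tol = 1e-9,
                            theta_focus = 2, theta_edge = 5) {
  as.list(environment())
}

stage <- function(manifest, name, code) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(code), error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  manifest$timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
  assign("manifest", manifest, envir = parent.frame())
  res
}

#' Run the full non-invasive reconstruction pipeline
#'
#' Simulates an acquisition from the configuration, then runs the complete
#' reconstruction: high-pass filtering, NMF demixing at (over)estimated
#' rank, spurious/duplicate rejection, per-row phase retrieval, phase
#' conjugation with non-invasive epi-variance validation, and
#' memory-effect imaging (displacement graph, stitching, rendering, MDS).
#' Artifacts of completed stages are written to `out_dir` (if given) as
#' they are produced, so a failing stage leaves prior results on disk.
#'
#' @param config list from [pipeline_config()] (partial lists are merged
#'   into the defaults).
#' @param emitters optional [emitter_map()]; default: random placement.
#' @param out_dir optional artifact directory.
#' @param imaging_source "epi" (default; epi frames recorded under the
#'   focusing patterns) or "W" (the raw NMF eigen-patterns) as input to the
#'   cross-correlation imaging.
#' @param verbose print stage progress.
#' @return list of class `specklemix_run`: `config`, `truth` (emitters, T,
#'   W), `stack`, `fit`, `t_est`, `report` (focus report), `graph`,
#'   `object_map`, `errors` (alignment to truth), `image`, `mds`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = list(), emitters = NULL, out_dir = NULL,
                         imaging_source = c("epi", "W"), verbose = FALSE) {
  imaging_source <- match.arg(imaging_source)
  def <- pipeline_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(def, config)
  say <- function(...) if (verbose) message(...)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  manifest <- list(config = cfg, seed = cfg$seed,
                   substreams = list(
                     patterns = substream_seed(cfg$seed, "patterns"),
                     field_tm = substream_seed(cfg$seed, "field_tm"),
                     intensity_tm = substream_seed(cfg$seed, "intensity_tm"),
                     noise = substream_seed(cfg$seed, "noise")),
                   versions = list(
                     specklemix = as.character(utils::packageVersion("specklemix")),
                     R = paste(R.version$major, R.version$minor, sep = ".")),
                   timings = list(), hashes = list())
  persist <- function(name, writer) {
    if (is.null(out_dir)) return(invisible(NULL))
    p <- file.path(out_dir, name)
    writer(p)
    manifest$hashes[[name]] <<- unname(tools::md5sum(p))
    yaml::write_yaml(manifest[setdiff(names(manifest), "config")],
                     file.path(out_dir, "manifest.yaml"))
    write_config(cfg, file.path(out_dir, "config.yaml"))
  }

  say("simulate")
  sim <- stage(manifest, "simulate", {
    sc <- simulation_config(cfg$n_targets, cfg$n_slm, cfg$grid,
                            cfg$n_patterns, cfg$me_range, cfg$speckle_grain,
                            cfg$excitation_exponent, cfg$photon_budget,
                            cfg$read_noise_sd, cfg$seed)
    em <- if (is.null(emitters)) random_emitters(cfg$n_targets, sc) else emitters
    patt <- generate_random_patterns(sc$n_slm, sc$n_patterns,
                                     substream_seed(cfg$seed, "patterns"))
    TT <- make_field_tm(sc, em)
    W <- make_intensity_tm(sc, em)
    stack <- simulate_acquisition(TT, W, patt, sc)
    list(sc = sc, em = em, patt = patt, TT = TT, W = W, stack = stack)
  })
  persist("stack.tiff", function(p) write_stack(sim$stack, p))
  persist("emitters.csv", function(p) write_emitters(sim$em, p))

  say("high-pass")
  hp <- stage(manifest, "highpass",
              high_pass_filter(sim$stack, cfg$highpass_sigma))

  rank <- cfg$rank
  if (is.null(rank)) {
    say("rank estimation")
    re <- stage(manifest, "estimate_rank",
                estimate_rank(hp, cfg$rank_max, seed = cfg$seed))
    # recommended usage: overestimate and prune afterwards
    rank <- min(2L * re$r_hat, min(dim(hp$images)))
    manifest$rank_estimate <- re$r_hat
  }

  say("NMF (rank ", rank, ")")
  fit <- stage(manifest, "nmf",
               nmf_factorize(hp, rank, n_iter_max = cfg$n_iter_max,
                             tol = cfg$nmf_tol, n_restarts = cfg$n_restarts,
                             seed = cfg$seed))
  say("selection")
  fit <- stage(manifest, "select",
               select_eigenpatterns(fit, cfg$theta_dup, cfg$theta_var))

  say("phase retrieval (", length(fit$kept), " rows)")
  pr <- stage(manifest, "phase_retrieval",
              retrieve_field_tm(fit$H[fit$kept, , drop = FALSE], sim$patt,
                                pr_config(n_iter_max = cfg$pr_iter,
                                          tol = cfg$pr_tol, seed = cfg$seed)))

  say("focusing + validation")
  report <- stage(manifest, "focusing", {
    rep <- focus_report(pr$matrix, sim$TT, sim$W, sim$sc,
                        theta_focus = cfg$theta_focus, seed = cfg$seed)
    rep$nmf_component <- fit$kept
    rep
  })

  # final component selection: epi verdicts mark spurious, validation-frame
  # correlations mark duplicates
  fit <- stage(manifest, "final_select", {
    epi_full <- rep(FALSE, fit$rank)
    epi_full[fit$kept] <- report$epi_verdict
    frames_full <- matrix(0, nrow(sim$W$matrix), fit$rank)
    frames_full[, fit$kept] <- attr(report, "epi_frames")
    select_eigenpatterns(fit, cfg$theta_dup, cfg$theta_var,
                         epi_ok = epi_full, frames = frames_full)
  })
  report$flag <- fit$flags[report$nmf_component]
  report$validated <- report$validated & report$flag == "valid"
  persist("focus_report.csv", function(p)
    utils::write.csv(report, p, row.names = FALSE))

  say("memory-effect imaging")
  imaging <- stage(manifest, "imaging", {
    keep <- which(report$validated)
    if (length(keep) >= 2) {
      if (imaging_source == "epi") {
        # epi frames recorded under the validated focusing patterns; the
        # mean frame under random illumination is subtracted to cancel the
        # common leak background shared by all focused frames
        pats <- vapply(keep, function(i)
          conjugate_focus_pattern(pr$matrix[i, ]), numeric(cfg$n_slm))
        exc <- function(Ph) {
          h <- Mod(sim$TT$matrix %*% exp(1i * Ph))^2
          if (cfg$excitation_exponent != 1) h <- h^cfg$excitation_exponent
          sim$W$matrix %*% h
        }
        src <- exc(pats)
        base_ph <- with_seed(substream_seed(cfg$seed, "epi-baseline"),
                             matrix(stats::runif(cfg$n_slm * 25, 0, 2 * pi),
                                    cfg$n_slm, 25))
        base <- exc(base_ph)
        src <- high_pass_filter(speckle_stack(src, cfg$grid),
                                cfg$highpass_sigma)$images
        base <- high_pass_filter(speckle_stack(base, cfg$grid),
                                 cfg$highpass_sigma)$images
        src <- src - rowMeans(base)
      } else {
        # NMF eigen-patterns come from the high-passed stack already
        src <- fit$W[, fit$kept[keep], drop = FALSE]
      }
      graph <- build_displacement_graph(src, cfg$grid, cfg$theta_edge)
      om <- tryCatch(stitch_positions(graph), error = function(e) NULL)
      img <- if (!is.null(om))
        assemble_image(om, grid = cfg$grid,
                       spot_sigma = cfg$speckle_grain / 2) else NULL
      errs <- if (!is.null(om))
        align_positions(om, cbind(sim$em$row, sim$em$col)[report$target[keep], ,
                                                          drop = FALSE])
        else NULL
      mds <- if (!is.null(om) && graph$n_nodes >= 3 &&
                 length(unique(graph$membership)) == 1)
        tryCatch(mds_localize(graph_distance_matrix(graph)),
                 error = function(e) NULL) else NULL
      list(graph = graph, object_map = om, image = img, errors = errs,
           mds = mds, components_used = keep)
    } else list(graph = NULL, object_map = NULL, image = NULL, errors = NULL,
                mds = NULL, components_used = keep)
  })
  if (!is.null(imaging$graph))
    persist("graph.csv", function(p) write_graph(imaging$graph, p))

  structure(list(config = cfg,
                 truth = list(emitters = sim$em, field_tm = sim$TT,
                              intensity_tm = sim$W),
                 patterns = sim$patt, stack = sim$stack, fit = fit,
                 t_est = pr, report = report, graph = imaging$graph,
                 object_map = imaging$object_map, errors = imaging$errors,
                 image = imaging$image, mds = imaging$mds,
                 manifest = manifest), class = "specklemix_run")
}

#' @export
print.specklemix_run <- function(x, ...) {
  cat(sprintf("<specklemix_run> N = %d | rank %d | kept %d | validated foci %d\n",
              x$config$n_targets, x$fit$rank, length(x$fit$kept),
              sum(x$report$validated, na.rm = TRUE)))
  if (!is.null(x$report)) {
    v <- x$report$snr[x$report$validated]
    if (length(v))
      cat(sprintf("  median focus SNR %.1f | distinct targets %d\n",
                  stats::median(v), length(unique(x$report$target[x$report$validated]))))
  }
  invisible(x)
}
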