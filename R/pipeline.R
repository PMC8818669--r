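#' Run the full per-case analysis workflow
#'
#' Orchestrates: CSA profiling, Huber-criterion detection, morphology
#' report, healthy reconstruction, virtual stent deployment, and
#' hemodynamic index summaries per provided field state
#' (fusiform/healthy/treated). Stages whose inputs are absent are skipped
#' and marked; stage errors are re-thrown with the stage name.
#'
#' @param cfg configuration list (or path to a JSON config):
#'   \describe{
#'     \item{case_id}{label.}
#'     \item{mesh / centerline}{`surface_mesh` and `centerline` objects or
#'       file paths (STL/OBJ, CSV).}
#'     \item{morphology}{list(spacing, n_rays, huber_ratio,
#'       proximal_window, distal_window); defaults 0.25 mm, 360, 1.5, 5, 5.}
#'     \item{smoothing}{list(lambda, iterations); defaults 0.5, 20.}
#'     \item{stent}{list(L_nom, D_nom, N_w, t_s, beta0, s_distal) or NULL.}
#'     \item{fields}{named list of states ("fusiform", "healthy",
#'       "treated"); each a list(wall = path/`wall_series`,
#'       volume = path/`volume_series`) or NULL.}
#'     \item{outdir}{optional output directory for JSON/CSV artifacts.}
#'     \item{seed}{integer seed recorded and used for any stochastic step.}
#'   }
#' @return list of class `case_report` with sections `morphology`, `stent`,
#'   `indices` (per state), `provenance` (config hash, seed) and `skipped`.
#' @export
run_case <- function(cfg) {
  if (is.character(cfg)) cfg <- jsonlite::read_json(cfg, simplifyVector = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  seed <- cfg$seed %||% 1L
  mp <- cfg$morphology %||% list()
  spacing <- mp$spacing %||% 0.25
  n_rays <- mp$n_rays %||% 360L
  huber <- mp$huber_ratio %||% 1.5
  pw <- mp$proximal_window %||% 5
  dw <- mp$distal_window %||% 5
  skipped <- character(0)
  report <- list(case_id = cfg$case_id %||% "case")

  mesh <- cl <- NULL
  if (!is.null(cfg$mesh)) {
    mesh <- stage("load_mesh",
                  if (is.character(cfg$mesh)) read_mesh(cfg$mesh)
                  else cfg$mesh)
    cl <- stage("load_centerline",
                if (is.character(cfg$centerline))
                  read_centerline(cfg$centerline)
                else cfg$centerline)
  }

  region <- profile <- NULL
  if (!is.null(mesh)) {
    profile <- stage("profile",
                     csa_profile(mesh, cl, spacing = spacing,
                                 n_rays = n_rays))
    d_nom <- stage("nominal_diameter",
                   nominal_diameter(profile, pw, dw))
    region <- stage("detect",
                    detect_fusiform(profile, d_nom, huber_ratio = huber))
    if (is.null(region)) {
      report$morphology <- list(detected = FALSE, d_nominal = d_nom)
    } else {
      mr <- stage("morphology_report", morphology_report(profile, region))
      report$morphology <- list(
        detected = TRUE, d_nominal = d_nom,
        CSA_A = mr$CSA_A, CSA_PV = mr$CSA_PV, RI = mr$RI,
        RI_pct = mr$RI_pct,
        s_start = region$s_start, s_end = region$s_end,
        ratio_max = region$ratio_max)
    }
  } else skipped <- c(skipped, "morphology (no mesh)")

  if (!is.null(mesh) && !is.null(region) &&
      !isFALSE(cfg$reconstruct %||% TRUE)) {
    sm <- cfg$smoothing %||% list()
    tgt <- stage("target_profile", target_radius_profile(profile, region))
    healthy_mesh <- stage("restore",
                          remove_dilation(mesh, cl, region, tgt,
                                          lambda = sm$lambda %||% 0.5,
                                          iterations = sm$iterations %||% 20L))
    report$healthy_mesh <- healthy_mesh
    if (!is.null(cfg$outdir))
      write_mesh(healthy_mesh, file.path(cfg$outdir, "healthy.stl"))
  }

  if (!is.null(cfg$stent) && !is.null(mesh)) {
    st <- cfg$stent
    spec <- stage("stent_spec",
                  stent_spec(st$L_nom, st$D_nom, st$N_w, st$t_s,
                             beta0 = st$beta0 %||% 75))
    dep <- stage("deploy",
                 deploy_stent(spec, mesh, cl, s_distal = st$s_distal,
                              profile = profile,
                              on_overexpansion = "cap"))
    app <- stage("apposition",
                 apposition_map(dep, mesh, cl,
                                threshold = st$threshold %||% 0.25,
                                stride = 2L))
    cov <- stage("coverage",
                 metal_coverage(dep, min(dep$s_samp), max(dep$s_samp)))
    report$stent <- list(L_dep = dep$L_dep, L_nom = spec$L_nom,
                         d_range = range(dep$d_samp),
                         malapposed_fraction = app$malapposed_fraction,
                         max_gap = app$max_gap, coverage = cov)
    report$deployed_stent <- dep
  } else if (!is.null(cfg$stent)) {
    skipped <- c(skipped, "stent (no mesh)")
  }

  states <- c("fusiform", "healthy", "treated")
  report$indices <- setNames(vector("list", length(states)), states)
  for (st_name in states) {
    f <- cfg$fields[[st_name]]
    if (is.null(f)) {
      report$indices[[st_name]] <- "absent"
      skipped <- c(skipped, sprintf("indices:%s (no fields)", st_name))
      next
    }
    res <- list()
    if (!is.null(f$wall)) {
      ws <- stage(paste0("indices:", st_name),
                  as_one_cycle(if (is.character(f$wall))
                    read_field_series(f$wall) else f$wall))
      a <- awss(ws); o <- osi(ws); r <- rrt(a, o)
      res$AWSS <- index_summary(a)
      res$OSI <- index_summary(o)
      res$RRT <- index_summary(r)
    }
    if (!is.null(f$volume)) {
      vs <- stage(paste0("indices:", st_name),
                  as_one_cycle(if (is.character(f$volume))
                    read_field_series(f$volume) else f$volume))
      res$OVI <- index_summary(ovi(vs))
      res$KE <- index_summary(kinetic_energy(vs)$avg)
    }
    report$indices[[st_name]] <- res
  }

  cfg_strip <- cfg[setdiff(names(cfg),
                           c("mesh", "centerline", "fields", "outdir"))]
  report$provenance <- list(
    package_version = as.character(utils::packageVersion("fusiflow")),
    seed = seed,
    config_hash = fnv1a(jsonlite::toJSON(cfg_strip, auto_unbox = TRUE,
                                         digits = 12)))
  report$skipped <- skipped
  class(report) <- "case_report"
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    write_case_report(report, cfg$outdir)
  }
  report
}

# trim to the final cycle when the series spans more than one period
as_one_cycle <- function(series) {
  span <- series$times[length(series$times)] - series$times[1L]
  if (span >= series$T) last_cycle(series) else series
}

#' Write a case report as JSON plus a one-row morphology CSV
#' @param report a `case_report`.
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_case_report <- function(report, outdir) {
  slim <- report[setdiff(names(report),
                         c("healthy_mesh", "deployed_stent"))]
  jsonlite::write_json(slim, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  if (!is.null(report$morphology) && isTRUE(report$morphology$detected)) {
    m <- report$morphology
    write.csv(data.frame(case = report$case_id, max_CSA_A = m$CSA_A,
                         CSA_PV = m$CSA_PV, RI_pct = m$RI_pct),
              file.path(outdir, "morphology.csv"), row.names = FALSE)
  }
  invisible(outdir)
}

#' @export
print.case_report <- function(x, ...) {
  cat(sprintf("<case_report> %s\n", x$case_id))
  if (!is.null(x$morphology)) {
    if (isTRUE(x$morphology$detected))
      cat(sprintf("  morphology: CSA_A %.2f, CSA_PV %.2f, RI %d%%\n",
                  x$morphology$CSA_A, x$morphology$CSA_PV,
                  x$morphology$RI_pct))
    else cat("  morphology: no dilation detected\n")
  }
  if (!is.null(x$stent))
    cat(sprintf("  stent: L_dep %.2f mm, malapposed %.1f%%, coverage %.3f\n",
                x$stent$L_dep, 100 * x$stent$malapposed_fraction,
                x$stent$coverage))
  for (s in names(x$indices))
    if (!identical(x$indices[[s]], "absent"))
      cat(sprintf("  indices[%s]: %s\n", s,
                  paste(names(x$indices[[s]]), collapse = ", ")))
  invisible(x)
}

#' Compare fusiform / healthy / treated index summaries
#'
#' For every index present in all three states, reports the
#' treated/fusiform and treated/healthy ratios of the chosen summary
#' statistic and flags indices where the treated state moved toward the
#' healthy state (`|treated - healthy| < |fusiform - healthy|`).
#'
#' @param fusiform,healthy,treated per-state index summaries: named lists
#'   (index -> list(mean, max, p95, wmean)), e.g. the `indices` entries of
#'   a `case_report`.
#' @param stat summary statistic to compare on (default "max").
#' @return object of class `comparison_report`: data.frame(index,
#'   fusiform, healthy, treated, treated_over_fusiform,
#'   treated_over_healthy, restored_toward_healthy).
#' @export
compare_states <- function(fusiform, healthy, treated, stat = "max") {
  idx <- Reduce(intersect, list(names(fusiform), names(healthy),
                                names(treated)))
  if (length(idx) == 0L) stop("mismatched regions: no common indices")
  rows <- lapply(idx, function(nm) {
    f <- fusiform[[nm]][[stat]]
    h <- healthy[[nm]][[stat]]
    t <- treated[[nm]][[stat]]
    ratio <- function(a, b) if (a == b) 1 else a / b
    data.frame(index = nm, fusiform = f, healthy = h, treated = t,
               treated_over_fusiform = ratio(t, f),
               treated_over_healthy = ratio(t, h),
               restored_toward_healthy = abs(t - h) < abs(f - h) |
                 (t == h & f == h))
  })
  out <- do.call(rbind, rows)
  attr(out, "stat") <- stat
  class(out) <- c("comparison_report", class(out))
  out
}
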