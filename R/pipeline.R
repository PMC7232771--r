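#' Read and validate a pipeline run configuration
#'
#' YAML configuration describing a full run: seascape grid, current
#' components, environmental gradients, release schedule, site placement,
#' connectivity analysis options, and demography. A bundled demo
#' configuration ships with the package:
#' `system.file("extdata", "demo_config.yaml", package = "seascapeConn")`.
#'
#' @param path YAML file path.
#' @return The configuration list (class `"RunConfig"`), with defaults filled.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (req in c("grid", "currents", "release", "analysis", "demography")) {
    if (is.null(cfg[[req]])) stop("config is missing section '", req, "'")
  }
  cfg$seed <- cfg$seed %||% 1L
  cfg$analysis$generations <- cfg$analysis$generations %||% 64L
  cfg$analysis$symmetrization <- cfg$analysis$symmetrization %||% "mean"
  cfg$analysis$theta_grid <- cfg$analysis$theta_grid %||% c(0.001, 0.002, 0.003)
  cfg$analysis$n_perm <- cfg$analysis$n_perm %||% 9999L
  cfg$sites <- cfg$sites %||% list(count = 25, n_regions = 5)
  structure(cfg, class = c("RunConfig", "list"))
}

# Rebuild the (deterministic) grid and field from a config.
config_seascape <- function(cfg) {
  grid <- buildGrid(cfg$grid)
  env <- cfg$environment
  if (!is.null(env$salinity)) {
    grid <- assignEnvironment(grid, "salinity", env$salinity$axis %||% "x",
                              env$salinity$from, env$salinity$to)
  }
  if (!is.null(env$temperature)) {
    grid <- assignEnvironment(grid, "temperature", env$temperature$axis %||% "y",
                              env$temperature$from, env$temperature$to)
  }
  field <- makeVelocityField(grid, cfg$currents$components,
                             seed = cfg$currents$seed %||% cfg$seed)
  list(grid = grid, field = field)
}

config_schedule <- function(cfg) {
  r <- cfg$release
  releaseSchedule(months = unlist(r$months) %||% 4:9,
                  particlesPerCell = r$particles_per_cell %||% 50,
                  pldDays = r$pld_days %||% 5,
                  dtS = r$dt_s %||% 3600)
}

need_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    stop("missing artifact '", basename(path), "': run stage '", stage,
         "' first", call. = FALSE)
  }
  path
}

#' Run the seascape-genetics pipeline
#'
#' Orchestrates the full inference chain, writing plain-text artifacts
#' (CSV/VCF/YAML) into `outDir`. Stages, in order:
#' \describe{
#'   \item{seascape}{build the grid, environment and velocity field
#'     (`grid.csv`).}
#'   \item{track}{Lagrangian dispersal simulation and the normalized
#'     single-generation connectivity matrix (`connectivity_cell_1gen.csv`).}
#'   \item{connect}{multigenerational accumulation, symmetrization, log
#'     transform, site placement and site-level aggregation (`sites.csv`,
#'     `connectivity_site_*.csv`).}
#'   \item{cluster}{barrier clustering of the symmetrized cell matrix over
#'     the threshold grid (`clusters.csv`, `barrier_strengths.csv`).}
#'   \item{genetics}{stepping-stone genotype simulation driven by the
#'     site-level connectivity, VCF export, diversity and pairwise FST
#'     (`genotypes.vcf`, `diversity.csv`, `fst.csv`, `mds.csv`).}
#'   \item{compare}{Mantel test of FST against log multigenerational
#'     connectivity, isolation-by-distance regressions, the
#'     heterozygosity-environment model and regional FST summaries
#'     (`mantel.yaml`, `ibd.csv`, `env_regression.csv`,
#'     `fst_regions_*.csv`).}
#' }
#' Stages run standalone re-derive deterministic inputs from the config and
#' read stochastic upstream artifacts from `outDir`, erroring with the name
#' of the required prior stage when one is missing. A `manifest.yaml` keyed
#' by stage records parameters, seeds and artifact checksums; a rerun with
#' the same config and seed reproduces every artifact byte for byte.
#'
#' @param config a [readRunConfig()] list.
#' @param outDir output directory (created if needed).
#' @param stages character vector of stages, or `"all"`.
#' @return Invisibly, a list of in-memory results keyed by stage.
#' @export
runPipeline <- function(config, outDir, stages = "all") {
  allStages <- c("seascape", "track", "connect", "cluster", "genetics",
                 "compare")
  if (identical(stages, "all")) stages <- allStages
  if (!all(stages %in% allStages)) {
    stop("unknown stage(s): ", paste(setdiff(stages, allStages), collapse = ", "))
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  manifestPath <- file.path(outDir, "manifest.yaml")
  manifest <- if (file.exists(manifestPath)) yaml::read_yaml(manifestPath) else list()
  note <- function(stage, params, files) {
    manifest[[stage]] <<- list(
      params = params, seed = config$seed,
      package_version = as.character(utils::packageVersion("seascapeConn")),
      artifacts = lapply(setNames(files, basename(files)), function(f)
        list(md5 = unname(tools::md5sum(f))))
    )
    yaml::write_yaml(manifest, manifestPath)
  }

  sea <- NULL
  get_sea <- function() {
    if (is.null(sea)) sea <<- config_seascape(config)
    sea
  }

  if ("seascape" %in% stages) {
    s <- get_sea()
    grid <- s$grid
    cc <- cellCenters(grid)
    df <- data.frame(
      cell = seq_along(grid@landMask),
      x_km = cc[, 1], y_km = cc[, 2],
      land = as.vector(grid@landMask),
      depth_m = as.vector(grid@depthM),
      habitat = as.vector(grid@habitatMask),
      salinity_psu = as.vector(grid@salinityPsu),
      temp_C = as.vector(grid@temperatureC),
      u_ms = as.vector(s$field@u), v_ms = as.vector(s$field@v)
    )
    f <- file.path(outDir, "grid.csv")
    write.csv(df, f, row.names = FALSE)
    note("seascape", config$grid, f)
    res$seascape <- s
  }

  if ("track" %in% stages) {
    s <- get_sea()
    sched <- config_schedule(config)
    ens <- runDispersal(s$grid, s$field, sched, seed = sub_seed(config$seed, 11L))
    conn <- ensembleToConnectivity(ens, s$grid)
    fC <- file.path(outDir, "connectivity_cell_1gen.csv")
    writeConnectivityCsv(conn, fC)
    fE <- file.path(outDir, "ensemble.csv")
    write.csv(ens@particles, fE, row.names = FALSE)
    note("track", unclass(sched), c(fC, fE))
    res$track <- list(ensemble = ens, connectivity = conn)
  }

  if ("connect" %in% stages) {
    s <- get_sea()
    conn <- if (!is.null(res$track)) res$track$connectivity else
      readConnectivityCsv(need_artifact(
        file.path(outDir, "connectivity_cell_1gen.csv"), "track"))
    G <- config$analysis$generations
    mode <- config$analysis$symmetrization
    multi <- multigenConnectivity(conn, G)
    sites <- placeSites(s$grid, config$sites$count, config$sites$n_regions)
    siteCells <- setNames(as.list(sites$cell), sites$site_id)
    site1 <- siteConnectivity(conn, siteCells)
    siteG <- siteConnectivity(multi, siteCells)
    siteGsym <- symmetrize(siteG, mode)
    fS <- file.path(outDir, "sites.csv")
    write.csv(sites, fS, row.names = FALSE)
    f1 <- file.path(outDir, "connectivity_site_1gen.csv")
    writeConnectivityCsv(site1, f1)
    fG <- file.path(outDir, sprintf("connectivity_site_%dgen_%s.csv", G, mode))
    writeConnectivityCsv(siteGsym, fG)
    fL <- file.path(outDir, sprintf("logconnectivity_site_%dgen_%s.csv", G, mode))
    lg <- logConnectivity(siteGsym)
    write.csv(data.frame(node_id = rownames(lg), lg, check.names = FALSE),
              fL, row.names = FALSE)
    note("connect", list(generations = G, symmetrization = mode), c(fS, f1, fG, fL))
    res$connect <- list(sites = sites, cell1 = conn, cellG = multi,
                        site1 = site1, siteGsym = siteGsym, logSiteG = lg)
  }

  if ("cluster" %in% stages) {
    conn <- if (!is.null(res$connect)) res$connect$cell1 else
      readConnectivityCsv(need_artifact(
        file.path(outDir, "connectivity_cell_1gen.csv"), "track"))
    symm <- symmetrize(conn, config$analysis$symmetrization)
    thetas <- config$analysis$theta_grid
    assignments <- lapply(thetas, function(t) clusterConnectivity(symm, t))
    lab <- data.frame(node_id = nodeIds(conn))
    for (k in seq_along(thetas)) {
      lab[[sprintf("cluster_theta_%g", thetas[k])]] <-
        unname(clusterLabels(assignments[[k]]))
    }
    fA <- file.path(outDir, "clusters.csv")
    write.csv(lab, fA, row.names = FALSE)
    fB <- file.path(outDir, "barrier_strengths.csv")
    strengths <- do.call(rbind, lapply(seq_along(thetas), function(k)
      cbind(theta = thetas[k], assignments[[k]]@strengths)))
    write.csv(strengths, fB, row.names = FALSE)
    note("cluster", list(theta_grid = thetas), c(fA, fB))
    res$cluster <- assignments
  }

  if ("genetics" %in% stages) {
    if (is.null(res$connect)) {
      sitesPath <- need_artifact(file.path(outDir, "sites.csv"), "connect")
      sites <- read.csv(sitesPath)
      site1 <- readConnectivityCsv(need_artifact(
        file.path(outDir, "connectivity_site_1gen.csv"), "connect"))
    } else {
      sites <- res$connect$sites
      site1 <- res$connect$site1
    }
    dm <- config$demography
    demo <- demographyConfig(
      N = dm$N %||% 100L, m = dm$m %||% 0.1, nLoci = dm$n_loci %||% 1000L,
      nGenerations = dm$n_generations %||% 200L,
      nIndPerSite = dm$n_ind_per_site %||% 20L,
      missingRate = dm$missing_rate %||% 0,
      seed = sub_seed(config$seed, 21L))
    gd <- simulateGenotypes(site1, demo, sites)
    fV <- file.path(outDir, "genotypes.vcf")
    writeVCF(gd, fV)
    div <- siteDiversity(gd)
    fst <- pairwiseFst(gd)
    mds <- metricMDS(fst$fst, k = 2)
    fD <- file.path(outDir, "diversity.csv")
    write.csv(div, fD, row.names = FALSE)
    fF <- file.path(outDir, "fst.csv")
    write.csv(data.frame(site_id = rownames(fst$fst), fst$fst,
                         check.names = FALSE), fF, row.names = FALSE)
    fM <- file.path(outDir, "mds.csv")
    write.csv(data.frame(site_id = rownames(mds$points), mds$points,
                         check.names = FALSE), fM, row.names = FALSE)
    note("genetics", unclass(demo), c(fV, fD, fF, fM))
    res$genetics <- list(dataset = gd, diversity = div, fst = fst, mds = mds)
  }

  if ("compare" %in% stages) {
    if (is.null(res$genetics)) {
      fstPath <- need_artifact(file.path(outDir, "fst.csv"), "genetics")
      fstDf <- read.csv(fstPath, check.names = FALSE)
      fstM <- as.matrix(fstDf[, -1]); dimnames(fstM) <- list(fstDf$site_id, fstDf$site_id)
      div <- read.csv(need_artifact(file.path(outDir, "diversity.csv"),
                                    "genetics"))
    } else {
      fstM <- res$genetics$fst$fst
      div <- res$genetics$diversity
    }
    G <- config$analysis$generations
    mode <- config$analysis$symmetrization
    if (is.null(res$connect)) {
      lgPath <- need_artifact(file.path(
        outDir, sprintf("logconnectivity_site_%dgen_%s.csv", G, mode)), "connect")
      lgDf <- read.csv(lgPath, check.names = FALSE)
      lg <- as.matrix(lgDf[, -1]); dimnames(lg) <- list(lgDf$node_id, lgDf$node_id)
      sites <- read.csv(file.path(outDir, "sites.csv"))
    } else {
      lg <- res$connect$logSiteG
      sites <- res$connect$sites
    }
    mt <- mantelTest(fstM, lg, nPerm = config$analysis$n_perm,
                     seed = sub_seed(config$seed, 31L))
    flagged <- unlist(config$analysis$flagged_sites) %||% character()
    ibd <- ibdRegression(fstM, lg, flagged)
    envPred <- intersect(c("salinity_psu", "temp_C", "coast_dist_km", "mpa"),
                         names(sites))
    envFit <- envRegression(div, sites, predictors = envPred)
    reg <- regionFstSummary(fstM, setNames(sites$region, sites$site_id))
    fMt <- file.path(outDir, "mantel.yaml")
    yaml::write_yaml(list(r = mt@r, p = mt@p, n_perm = mt@nPerm,
                          symmetrization = mode, generations = G), fMt)
    fI <- file.path(outDir, "ibd.csv")
    ibdRows <- do.call(rbind, lapply(c("flagged", "rest"), function(gp) {
      g <- ibd[[gp]]
      if (is.null(g)) return(NULL)
      data.frame(group = gp, slope = g$slope, intercept = g$intercept,
                 r2 = g$r2, p = g$p, n = g$n)
    }))
    write.csv(ibdRows %||% data.frame(), fI, row.names = FALSE)
    fEn <- file.path(outDir, "env_regression.csv")
    write.csv(envFit@anovaTable, fEn, row.names = FALSE)
    fRw <- file.path(outDir, "fst_regions_within.csv")
    fRb <- file.path(outDir, "fst_regions_between.csv")
    write.csv(reg$within, fRw, row.names = FALSE)
    write.csv(reg$between, fRb, row.names = FALSE)
    note("compare", list(n_perm = config$analysis$n_perm), c(fMt, fI, fEn, fRw, fRb))
    res$compare <- list(mantel = mt, ibd = ibd, env = envFit, regions = reg)
  }

  invisible(res)
}
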