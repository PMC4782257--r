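#' Run the full shape-diversity / lability pipeline
#'
#' End-to-end orchestration, per skull region: Procrustes superimposition of
#' the region's landmark subset (with semi-landmark sliding), tangent
#' projection, the contrast-based allometry test with permutation inference
#' (and, by default, size correction only where significant), evolutionary
#' model fitting with AIC selection, the pooled multivariate rate
#' sigma^2_mult, shape disparity P^2, ancestral reconstruction, the
#' mean-standardized P-matrix, and random-skewers lability indexes.
#'
#' `config` is a list (or path to a YAML file) with elements:
#' \describe{
#'   \item{newick_path / tree}{tree file or `ape::phylo` object.}
#'   \item{groups}{named list; each group has `tps` (path) or `configs`
#'     (in-memory list), `template` (template name or `shape_template`), and
#'     optionally `regions` (named list of 1-based landmark index vectors;
#'     defaults to the template's region partition).}
#'   \item{n_permutations}{allometry permutations (default 10000).}
#'   \item{n_skewers}{random selection gradients (default 1000).}
#'   \item{seed}{master seed (default 1).}
#'   \item{model_menu}{character vector of candidate models, or a named list
#'     per region (default all five).}
#'   \item{size_correction_policy}{`"if_significant"` (default),
#'     `"always"`, `"never"`.}
#'   \item{pmatrix_source}{`"ancestral_nodes"` (default) or `"contrasts"`.}
#'   \item{standardize}{mean-standardize the P-matrix (default TRUE).}
#'   \item{outdir}{if non-NULL, per-stage intermediates and provenance are
#'     written there.}
#' }
#'
#' @param config configuration list or YAML path.
#' @return list with `results` (one data-frame row per region), `details`
#'   (per-region fitted objects), and `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  cfg$n_permutations <- cfg$n_permutations %||% 10000L
  cfg$n_skewers <- cfg$n_skewers %||% 1000L
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$model_menu <- cfg$model_menu %||% c("BM", "OU", "EB", "delta", "delta_OU")
  cfg$size_correction_policy <- cfg$size_correction_policy %||% "if_significant"
  cfg$pmatrix_source <- cfg$pmatrix_source %||% "ancestral_nodes"
  cfg$standardize <- cfg$standardize %||% TRUE
  cfg$pca_var <- cfg$pca_var %||% 0.95
  tree <- if (!is.null(cfg$tree)) cfg$tree
          else parse_newick(paste(readLines(cfg$newick_path), collapse = ""))
  outdir <- cfg$outdir
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  results <- list(); details <- list()
  region_i <- 0L
  for (g in names(cfg$groups)) {
    grp <- cfg$groups[[g]]
    tpl <- grp$template
    if (is.character(tpl)) tpl <- shape_template(tpl)
    configs <- if (!is.null(grp$configs)) grp$configs else read_tps(grp$tps)
    ids <- vapply(configs, `[[`, character(1), "specimen_id")
    in_tree <- ids %in% tree$tip.label
    if (sum(in_tree) < 10L)
      stop("group ", g, ": fewer than 10 species shared with the tree; ",
           "missing from tree: ",
           paste(utils::head(ids[!in_tree], 20), collapse = ", "))
    if (any(!in_tree))
      warning("group ", g, ": dropping ", sum(!in_tree),
              " species absent from the tree: ",
              paste(ids[!in_tree], collapse = ", "))
    configs <- configs[in_tree]
    ids <- ids[in_tree]
    gtree <- ape::keep.tip(tree, ids)
    regions <- grp$regions %||% tpl$region_partition
    for (rg in names(regions)) {
      region_i <- region_i + 1L
      rseed <- cfg$seed + 101L * region_i
      label <- if (length(cfg$groups) > 1L) paste(g, rg, sep = ".") else rg
      idx <- as.integer(regions[[rg]])
      rtpl <- subset_template(tpl, idx)
      rconf <- lapply(configs, function(cf)
        list(specimen_id = cf$specimen_id,
             points = cf$points[idx, , drop = FALSE]))
      row <- analyze_region(rconf, rtpl, gtree, region = label, cfg = cfg,
                            seed = rseed, outdir = outdir)
      results[[label]] <- row$row
      details[[label]] <- row$detail
    }
  }
  res <- do.call(rbind, results)
  rownames(res) <- NULL
  prov <- list(package_version = as.character(utils::packageVersion("morpholab")),
               r_version = R.version.string,
               seed = cfg$seed,
               n_permutations = cfg$n_permutations,
               n_skewers = cfg$n_skewers,
               size_correction_policy = cfg$size_correction_policy,
               pmatrix_source = cfg$pmatrix_source,
               standardize = cfg$standardize,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (!is.null(outdir)) {
    utils::write.csv(res, file.path(outdir, "results.csv"), row.names = FALSE)
    writeLines(paste0(names(prov), "=", unlist(lapply(prov, as.character))),
               file.path(outdir, "provenance.txt"))
  }
  list(results = res, details = details, provenance = prov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one region: morphometrics -> allometry -> models -> lability
analyze_region <- function(rconf, rtpl, gtree, region, cfg, seed, outdir = NULL) {
  aligned <- gpa_align(rconf, region = region)
  if (length(rtpl$semi_idx))
    aligned <- slide_semilandmarks(aligned, rtpl)
  Y <- aligned$tangent_coords
  colnames(Y) <- paste0(rep(c("x", "y"), ncol(Y) / 2),
                        rep(seq_len(ncol(Y) / 2), each = 2))
  log_cs <- log(aligned$centroid_sizes)
  names(log_cs) <- aligned$specimen_ids
  btree <- resolve_polytomies(gtree, seed = seed)
  # allometry on contrasts
  pics <- pic_matrix(btree, Y)
  size_pic <- pic_matrix(btree, matrix(log_cs, ncol = 1,
                                       dimnames = list(names(log_cs), "logCS")))
  fit_a <- fit_allometry(pics$contrasts, size_pic$contrasts[, 1])
  perm <- permutation_test(pics$contrasts, size_pic$contrasts[, 1],
                           n_perm = cfg$n_permutations, seed = seed + 1L)
  policy <- cfg$size_correction_policy
  corrected <- switch(policy,
                      always = TRUE,
                      never = FALSE,
                      if_significant = perm$p_value < 0.05,
                      stop("unknown size_correction_policy: ", policy))
  Yc <- if (corrected) size_correct(Y, log_cs, fit_a$coefficients) else Y
  # evolutionary models
  menu <- cfg$model_menu
  if (is.list(menu)) menu <- menu[[region]] %||% c("BM", "OU", "EB", "delta", "delta_OU")
  Nsp <- nrow(Yc); q <- ncol(Yc)
  Yfit <- if (q > Nsp / 2) reduce_dimensions(Yc, cfg$pca_var) else Yc
  fits <- lapply(menu, function(m) fit_model(Yfit, btree, m))
  sel <- if (length(fits) >= 2L) select_model(fits) else list(best = fits[[1]], table = NULL)
  best <- sel$best
  s2m <- sigma_mult(Yc, btree)
  p2 <- mean_sq_procrustes_distance(Yc)
  # ancestral reconstruction and lability
  anc <- ancestral_states(btree, Yc)
  Pm <- if (cfg$pmatrix_source == "contrasts")
    build_p_matrix(pic_matrix(btree, Yc)$contrasts, source = "contrasts",
                   trait_means = anc[1, ])
  else build_p_matrix(anc, source = "ancestral_nodes")
  Puse <- if (isTRUE(cfg$standardize)) mean_standardize(Pm) else Pm
  sk <- random_skewers(Puse, n_vectors = cfg$n_skewers, seed = seed + 2L)
  row <- data.frame(
    region = region,
    n_species = Nsp,
    pct_var_size = fit_a$percent_variance,
    p_size = perm$p_value,
    size_corrected = corrected,
    best_model = best$model,
    delta = best$delta,
    alpha = best$alpha,
    r = best$r,
    sigma2 = best$sigma2,
    P2 = p2,
    sigma2_mult = s2m,
    respondability = sk$respondability,
    evolvability = sk$evolvability,
    flexibility = sk$flexibility,
    stringsAsFactors = FALSE
  )
  if (!is.null(outdir)) {
    pre <- file.path(outdir, region)
    utils::write.csv(data.frame(specimen_id = aligned$specimen_ids, Y,
                                check.names = FALSE),
                     paste0(pre, "_tangent.csv"), row.names = FALSE)
    utils::write.csv(data.frame(node = rownames(pics$contrasts),
                                pics$contrasts, check.names = FALSE),
                     paste0(pre, "_contrasts.csv"), row.names = FALSE)
    if (!is.null(sel$table))
      utils::write.csv(sel$table, paste0(pre, "_model_fits.csv"),
                       row.names = FALSE)
    utils::write.csv(as.data.frame(Puse$matrix), paste0(pre, "_pmatrix.csv"),
                     row.names = FALSE)
  }
  list(row = row,
       detail = list(aligned = aligned, allometry = fit_a, permutation = perm,
                     fits = fits, selection = sel, p_matrix = Puse,
                     skewers = sk, ancestral = anc, tree = btree,
                     tangent = Yc, log_sizes = log_cs))
}

#' Compare two skull regions
#'
#' Ratios (region A over region B) of disparity P^2, rate sigma^2_mult, and
#' the three lability indexes -- the quantities used to ask whether the more
#' diverse region is also the faster-evolving or more labile one.
#'
#' @param results the `results` data frame from [run_pipeline()].
#' @param region_a,region_b region names present in `results`.
#' @return one-row data frame of ratios.
#' @export
compare_regions <- function(results, region_a, region_b) {
  ia <- match(region_a, results$region)
  ib <- match(region_b, results$region)
  if (is.na(ia) || is.na(ib)) stop("region not found in results")
  rat <- function(col) results[[col]][ia] / results[[col]][ib]
  data.frame(region_a = region_a, region_b = region_b,
             P2_ratio = rat("P2"),
             sigma2_mult_ratio = rat("sigma2_mult"),
             respondability_ratio = rat("respondability"),
             evolvability_ratio = rat("evolvability"),
             flexibility_ratio = rat("flexibility"),
             stringsAsFactors = FALSE)
}
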