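#' Simulate paired human and mouse studies with planted structure
#'
#' Generates two-species expression data whose latent structure mirrors what
#' the pipeline assumes about real cohorts: a disease axis shared between
#' species, an age axis only partially shared, a human-specific (sex-linked)
#' confounder axis, and i.i.d. Gaussian noise. Every planted quantity is
#' recorded so downstream stages can be checked for parameter recovery.
#'
#' Human sample profile:
#' `x = beta_d * d * u_d + beta_a * age_std * u_a + beta_s * sex * u_s + noise`,
#' with `d` binary disease, `age_std` the standardized age and `sex` a 0/1
#' indicator. Mouse sample profile:
#' `y = dose_effect * dose * u_d + mouse_age_effect * age_std * u_a_mouse + noise`,
#' with genotype dose 0/1/2 and `u_a_mouse` sharing `age_share` of its
#' squared mass with the human age axis. Each effect vector `u` carries
#' per-gene weights of order 1 on its support genes and (for the disease
#' axis) a small dense background, so `beta_d = 2` means affected genes
#' separate disease from control by roughly 2-3 noise standard deviations —
#' the scale on which per-gene effect sizes are quoted in expression
#' studies. The recorded truth axes `w_*` are the unit-normalized
#' directions. The planted gene set is the `planted_size` genes carrying the
#' largest disease-axis weights (constructed positive, so they concentrate
#' in the top loading tail of a disease-aligned component); decoy sets are
#' size-matched uniform draws.
#'
#' @param n_genes Gene universe size (default 2000).
#' @param n_human_per_class Human samples per disease class (default 30).
#' @param n_mouse_per_group Mouse samples per genotype x age cell (default
#'   10; with 3 genotypes and 4 ages, 120 mice).
#' @param mouse_ages Mouse age levels in months (default 2, 4, 8, 18).
#' @param beta_d Human per-gene disease effect in noise-sd units (default 2).
#' @param beta_a Human age effect per standardized-age unit (default 1).
#' @param beta_s Human sex-confounder effect (default 0.5).
#' @param dose_effect Mouse disease effect per genotype dose unit (default 1,
#'   so homozygotes shift by 2, matching the human disease shift).
#' @param mouse_age_effect Mouse age effect per standardized-age unit
#'   (default 1).
#' @param age_share Fraction of the mouse age axis' squared mass shared with
#'   the human age axis (default 0.5).
#' @param sigma Noise standard deviation (default 1).
#' @param planted_size Planted (disease-affected) gene count (default 200,
#'   i.e. 10 percent of the default universe — the order of magnitude seen
#'   in hippocampal disease cohorts).
#' @param n_age_genes,n_sex_genes Support sizes of the age and sex axes
#'   (defaults 400 and 100).
#' @param n_decoy_sets Number of decoy gene sets (default 10).
#' @param shuffled_map If `TRUE`, mouse genes get distinct identifiers and a
#'   shuffled row order, exercising the homolog-mapping code path; by default
#'   the map is the identity pairing.
#' @param seed Optional integer seed; generation is bit-reproducible under a
#'   fixed seed.
#' @return A `synthetic_bundle`: `human` and `mouse` [expression_study()]s,
#'   `map` (`homolog_map`), `sets` (`gene_set_collection`, planted set named
#'   `"planted"`), and `truth` (axes, planted genes, parameters, seed).
#' @export
simulate_cross_species <- function(n_genes = 2000, n_human_per_class = 30,
                                   n_mouse_per_group = 10,
                                   mouse_ages = c(2, 4, 8, 18),
                                   beta_d = 2, beta_a = 1, beta_s = 0.5,
                                   dose_effect = 1, mouse_age_effect = 1,
                                   age_share = 0.5, sigma = 1,
                                   planted_size = 200, n_age_genes = 400,
                                   n_sex_genes = 100, n_decoy_sets = 10,
                                   shuffled_map = FALSE, seed = NULL) {
  if (n_genes < 50) stop("config error: need n_genes >= 50", call. = FALSE)
  if (n_human_per_class < 2 || n_mouse_per_group < 2) {
    stop("config error: all group sizes must be >= 2", call. = FALSE)
  }
  if (planted_size >= n_genes / 2) {
    stop("config error: planted_size must be < n_genes / 2", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  n_age_genes <- min(n_age_genes, n_genes)
  n_sex_genes <- min(n_sex_genes, n_genes)

  # disease effect vector: order-1 positive weights on the planted genes,
  # small dense background elsewhere
  planted_idx <- sort(sample.int(n_genes, planted_size))
  u_d <- stats::rnorm(n_genes, 0, 0.05)
  u_d[planted_idx] <- stats::runif(planted_size, 1, 1.5)
  u_a <- .support_vector(n_genes, n_age_genes)
  u_s <- .support_vector(n_genes, n_sex_genes)
  u_a_own <- .support_vector(n_genes, n_age_genes)
  u_a_mouse <- sqrt(age_share) * u_a + sqrt(1 - age_share) * u_a_own

  # human cohort: binary disease, uniform elderly ages, random sex
  n_h <- 2 * n_human_per_class
  d <- rep(c(0, 1), each = n_human_per_class)
  age_h <- round(stats::runif(n_h, 60, 95))
  sex_h <- sample(c("F", "M"), n_h, replace = TRUE)
  age_h_std <- as.numeric(scale(age_h))
  Xh <- outer(u_d, beta_d * d) + outer(u_a, beta_a * age_h_std) +
    outer(u_s, beta_s * as.integer(sex_h == "M")) +
    matrix(stats::rnorm(n_genes * n_h, 0, sigma), n_genes, n_h)
  h_ids <- sprintf("h%03d", seq_len(n_h))
  dimnames(Xh) <- list(genes, h_ids)
  human <- expression_study(
    Xh,
    tibble::tibble(sample_id = h_ids, age = age_h, sex = sex_h,
                   disease_label = ifelse(d == 1, "AD", "control"),
                   disease_code = as.integer(d)),
    species = "human"
  )

  # mouse cohort: genotype dose x age grid
  grid <- expand.grid(dose = 0:2, age = mouse_ages)
  dose <- rep(grid$dose, each = n_mouse_per_group)
  age_m <- rep(grid$age, each = n_mouse_per_group)
  n_m <- length(dose)
  sex_m <- sample(c("F", "M"), n_m, replace = TRUE)
  age_m_std <- as.numeric(scale(age_m))
  Xm <- outer(u_d, dose_effect * dose) +
    outer(u_a_mouse, mouse_age_effect * age_m_std) +
    matrix(stats::rnorm(n_genes * n_m, 0, sigma), n_genes, n_m)
  m_ids <- sprintf("m%03d", seq_len(n_m))
  mouse_genes <- genes
  if (shuffled_map) {
    mouse_genes <- paste0("mus_", genes)   # row i is genes[i]'s homolog
    ord <- sample.int(n_genes)             # shuffle row order to exercise alignment
    Xm <- Xm[ord, , drop = FALSE]
    mouse_genes <- mouse_genes[ord]
  }
  dimnames(Xm) <- list(mouse_genes, m_ids)
  mouse <- expression_study(
    Xm,
    tibble::tibble(sample_id = m_ids, age = age_m, sex = sex_m,
                   disease_label = c("WT", "HET", "HO")[dose + 1],
                   disease_code = as.integer(dose)),
    species = "mouse"
  )

  map <- if (shuffled_map) homolog_map(genes, paste0("mus_", genes))
         else homolog_map(genes, genes)

  planted_genes <- genes[planted_idx]
  sets <- c(list(planted = planted_genes),
            stats::setNames(
              lapply(seq_len(n_decoy_sets),
                     function(i) sort(sample(genes, planted_size))),
              sprintf("decoy%02d", seq_len(n_decoy_sets))))
  sets <- gene_set_collection(sets)

  truth <- list(
    gene_ids = genes,
    w_d = u_d / sqrt(sum(u_d^2)),
    w_a = u_a / sqrt(sum(u_a^2)),
    w_s = u_s / sqrt(sum(u_s^2)),
    w_a_mouse = u_a_mouse / sqrt(sum(u_a_mouse^2)),
    effect_vectors = list(u_d = u_d, u_a = u_a, u_s = u_s,
                          u_a_mouse = u_a_mouse),
    planted_genes = planted_genes,
    params = list(beta_d = beta_d, beta_a = beta_a, beta_s = beta_s,
                  dose_effect = dose_effect,
                  mouse_age_effect = mouse_age_effect,
                  age_share = age_share, sigma = sigma),
    seed = seed
  )
  structure(list(human = human, mouse = mouse, map = map, sets = sets,
                 truth = truth),
            class = "synthetic_bundle")
}

# effect vector with standard-normal weights on `k` support genes
.support_vector <- function(n, k) {
  v <- numeric(n)
  v[sample.int(n, k)] <- stats::rnorm(k)
  v
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("<synthetic_bundle>\n  human: ", ncol(x$human$values), " samples, mouse: ",
      ncol(x$mouse$values), " samples, ", nrow(x$human$values), " genes\n",
      "  planted set: ", length(x$truth$planted_genes), " genes\n", sep = "")
  invisible(x)
}

#' Alignment of fitted components with planted axes
#'
#' Absolute cosine similarity between each retained loading column and each
#' planted axis; sign flips of either vector leave it unchanged.
#'
#' @param model A `pca_space` fitted on the bundle's gene universe.
#' @param truth The `truth` element of a `synthetic_bundle` (or the bundle
#'   itself).
#' @return A tibble with columns `component`, `axis`, `cosine`.
#' @export
axis_alignment <- function(model, truth) {
  if (inherits(truth, "synthetic_bundle")) truth <- truth$truth
  if (!identical(model$gene_order, truth$gene_ids)) {
    if (!setequal(model$gene_order, truth$gene_ids)) {
      stop("gene-universe mismatch between model and truth", call. = FALSE)
    }
  }
  axes <- list(disease = truth$w_d, age = truth$w_a, sex = truth$w_s,
               mouse_age = truth$w_a_mouse)
  ord <- match(model$gene_order, truth$gene_ids)
  purrr::map_dfr(names(axes), function(ax) {
    w <- axes[[ax]][ord]
    cosines <- abs(as.numeric(crossprod(model$loadings, w))) /
      (sqrt(colSums(model$loadings^2)) * sqrt(sum(w^2)))
    tibble::tibble(component = colnames(model$loadings), axis = ax,
                   cosine = cosines)
  })
}
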