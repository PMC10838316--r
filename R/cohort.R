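#' Stroke lesion specification
#'
#' A spherical lesion with a location class. Classes follow the cohort
#' taxonomy: `cortical` lesions involve cortical structures (the sphere
#' intersects the gray-matter shell), `subcortical` lesions are confined
#' to white matter, `brainstem` lesions sit near the inferior core.
#'
#' @param center lesion centre (mm).
#' @param radius lesion radius (mm), >= 0.
#' @param location_class `"cortical"`, `"subcortical"` or `"brainstem"`.
#' @return object of class `lesion_spec`.
#' @export
lesion_spec <- function(center, radius,
                        location_class = c("cortical", "subcortical",
                                           "brainstem")) {
  location_class <- match.arg(location_class)
  if (radius < 0) stop("lesion radius must be >= 0")
  structure(list(center = as.numeric(center), radius = radius,
                 location_class = location_class),
            class = "lesion_spec")
}

#' Insert a stroke lesion into a head model
#'
#' Relabels every tetrahedron whose centroid lies inside the lesion
#' sphere as `lesion` (conductivity 0.8087 S/m by default). Only labels
#' change: mesh topology and total volume are conserved exactly.
#'
#' @param head a `head_model`.
#' @param lesion a [lesion_spec()].
#' @return the lesioned `head_model`, with the spec stored as
#'   `head$lesion`.
#' @export
insert_lesion <- function(head, lesion) {
  stopifnot(inherits(lesion, "lesion_spec"))
  r_head <- max(row_norms(head$mesh$nodes))
  if (sqrt(sum(lesion$center^2)) > r_head) {
    stop("out-of-domain error: lesion centre lies outside the skin surface")
  }
  if (lesion$radius > 0) {
    cen <- tet_centroids(head$mesh)
    inside <- row_norms(sweep(cen, 2L, lesion$center)) <= lesion$radius
    head$mesh$labels[inside] <- "lesion"
  }
  head$lesion <- lesion
  head
}

# Deterministic per-subject seed from the master seed (documented counter
# scheme; kept below 2^31).
subject_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) * 1009 + i) %% 2147483647)
}

#' Generate a synthetic stroke cohort
#'
#' Draws per-subject lesion geometry, demographics and initial motor
#' scores, emulating the structure of a hemiplegic stroke cohort:
#' configurable lesion-location class counts (default 8 cortical, 11
#' subcortical, 2 brainstem of 21), lesion spheres placed per class
#' (cortical centred at 0.9 x the gray-matter outer radius on the
#' affected side so they straddle the cortex; subcortical at 0.5 x,
#' confined to white matter; brainstem near the inferior pole), and
#' FMA-UE scores generated as
#' `clip(round(intercept - k * volume^(1/3) - b * 1[cortical] + noise), 0, 66)`
#' so that larger and more cortical lesions give lower scores.
#'
#' @param n cohort size.
#' @param class_counts named counts for `cortical`, `subcortical`,
#'   `brainstem`; must sum to `n`.
#' @param effect_params list with `intercept` (default 40), `k` (1.2),
#'   `b` (10), `sd` (5) of the FMA-UE model.
#' @param seed master seed; the whole cohort is reproducible from it.
#' @param head_params list passed to [build_layered_sphere_head()]
#'   (`layer_radii`, `conductivities`, `mesh_size`).
#' @param build_heads build a lesioned `head_model` per subject (set
#'   FALSE to draw covariates only, e.g. for large calibration samples).
#' @return object of class `tdcs_cohort`: `covariates` (tibble, one row
#'   per subject), `heads` (list of `head_model` or NULL), `params`.
#' @export
generate_synthetic_cohort <- function(n = 21,
                                      class_counts = c(cortical = 8,
                                                       subcortical = 11,
                                                       brainstem = 2),
                                      effect_params = list(),
                                      seed = 1L,
                                      head_params = list(),
                                      build_heads = TRUE) {
  if (sum(class_counts) != n) {
    stop("config error: `class_counts` must sum to `n`")
  }
  ep <- utils::modifyList(
    list(intercept = 40, k = 1.2, b = 10, sd = 5), effect_params
  )
  hp <- utils::modifyList(
    list(layer_radii = c(92, 86, 80, 78, 70),
         conductivities = conductivity_map(), mesh_size = 9),
    head_params
  )
  r_gray <- hp$layer_radii[4L]
  r_white <- hp$layer_radii[5L]
  classes <- rep(names(class_counts), class_counts)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    si <- subject_seed(seed, i)
    set.seed(si)
    cls <- classes[i]
    affected <- sample(c("left", "right"), 1L)
    sgn <- if (affected == "left") -1 else 1
    hand_dir <- c(sgn * sin(0.2 * pi), 0, cos(0.2 * pi))
    if (cls == "cortical") {
      dir <- hand_dir + rnorm(3L, sd = 0.25)
      dir[1L] <- sgn * abs(dir[1L])
      dir <- dir / sqrt(sum(dir^2))
      center <- dir * 0.9 * r_gray
      radius <- runif(1L, 6, 10) # straddles the cortex, stays out of the skull
    } else if (cls == "subcortical") {
      dir <- hand_dir + rnorm(3L, sd = 0.4)
      dir[1L] <- sgn * abs(dir[1L])
      dir <- dir / sqrt(sum(dir^2))
      center <- dir * 0.5 * r_gray
      radius <- runif(1L, 5, 12)
      radius <- min(radius, r_white - sqrt(sum(center^2)) - 1) # stay in white
    } else {
      dir <- c(0, -0.2, -1) + rnorm(3L, sd = 0.1)
      dir <- dir / sqrt(sum(dir^2))
      center <- dir * 0.65 * r_white
      radius <- runif(1L, 4, 8)
    }
    vol <- 4 / 3 * pi * radius^3
    fma <- ep$intercept - ep$k * vol^(1 / 3) -
      ep$b * (cls == "cortical") + rnorm(1L, sd = ep$sd)
    fma <- as.integer(pmin(66, pmax(0, round(fma))))
    rows[[i]] <- tibble::tibble(
      subject_id = sprintf("S%02d", i),
      class = cls,
      affected_side = affected,
      lesion_x = center[1L], lesion_y = center[2L], lesion_z = center[3L],
      lesion_r = radius,
      lesion_volume = vol,
      fma_ue = fma,
      age = as.integer(pmin(85, pmax(30, round(rnorm(1L, 59, 10))))),
      sex = sample(c("M", "F"), 1L, prob = c(0.67, 0.33)),
      seed = si
    )
  }
  covariates <- dplyr::bind_rows(rows)

  heads <- NULL
  if (build_heads) {
    base <- list(
      left = build_layered_sphere_head(
        layer_radii = hp$layer_radii, conductivities = hp$conductivities,
        mesh_size = hp$mesh_size, affected_side = "left", seed = seed
      ),
      right = build_layered_sphere_head(
        layer_radii = hp$layer_radii, conductivities = hp$conductivities,
        mesh_size = hp$mesh_size, affected_side = "right", seed = seed
      )
    )
    heads <- lapply(seq_len(n), function(i) {
      cv <- covariates[i, ]
      insert_lesion(
        base[[cv$affected_side]],
        lesion_spec(c(cv$lesion_x, cv$lesion_y, cv$lesion_z), cv$lesion_r,
                    cv$class)
      )
    })
  }
  structure(
    list(covariates = covariates, heads = heads,
         params = list(n = n, class_counts = class_counts,
                       effect_params = ep, head_params = hp, seed = seed)),
    class = "tdcs_cohort"
  )
}

#' @export
print.tdcs_cohort <- function(x, ...) {
  cat(sprintf("<tdcs_cohort> %d subjects (%s), seed %d\n",
              nrow(x$covariates),
              paste(sprintf("%s=%d", names(x$params$class_counts),
                            x$params$class_counts), collapse = ", "),
              x$params$seed))
  print(x$covariates)
  invisible(x)
}
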