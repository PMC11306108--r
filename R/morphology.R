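# Shape descriptors from the gyration tensor, in the standard polymer-physics
# definitions: for sorted eigenvalues l1 >= l2 >= l3,
#   asphericity  b = l1 - (l2 + l3) / 2
#   acylindricity c = l2 - l3
#   relative shape anisotropy kappa^2 = (b^2 + 0.75 c^2) / Rg^4
# kappa^2 is 0 for spherically symmetric objects and 1 for an ideal rod.

#' Feature columns fed to the classifier, in persisted order
#' @export
feature_columns <- function() {
  c("rg2", "lambda1", "lambda2", "lambda3", "asphericity", "acylindricity",
    "kappa2", "sphere_ratio", "mean_Id", "max_Id")
}

#' Gyration tensor of a voxel set
#'
#' `S_mn = (1/N) sum_p (r_p,m - rbar_m)(r_p,n - rbar_n)` over voxel-center
#' coordinates (voxel units, unweighted by intensity — intensity enters the
#' feature vector separately).
#'
#' @param voxels `n x 3` numeric matrix of voxel coordinates (z, y, x).
#' @return Symmetric positive semidefinite 3x3 matrix.
#' @export
gyration_tensor <- function(voxels) {
  voxels <- as.matrix(voxels)
  if (nrow(voxels) == 0L) stop("empty voxel set", call. = FALSE)
  if (ncol(voxels) != 3L) stop("`voxels` must have 3 columns", call. = FALSE)
  centered <- sweep(voxels, 2L, colMeans(voxels))
  crossprod(centered) / nrow(voxels)
}

# Features for one voxel set; returns a named list.
shape_features_one <- function(voxels) {
  s <- gyration_tensor(voxels)
  lam <- sort(pmax(eigen(s, symmetric = TRUE, only.values = TRUE)$values, 0),
              decreasing = TRUE)
  rg2 <- sum(lam)
  b <- lam[1L] - (lam[2L] + lam[3L]) / 2
  cc <- lam[2L] - lam[3L]
  kappa2 <- if (rg2 > 0) (b^2 + 0.75 * cc^2) / rg2^2 else 0
  sphere_ratio <- if (rg2 > 0) nrow(as.matrix(voxels)) / (4 * pi / 3 * rg2^1.5) else 0
  list(rg2 = rg2, lambda1 = lam[1L], lambda2 = lam[2L], lambda3 = lam[3L],
       asphericity = b, acylindricity = cc,
       kappa2 = min(max(kappa2, 0), 1), sphere_ratio = sphere_ratio)
}

#' Morphology features for candidate objects
#'
#' Computes, per object, the gyration-tensor eigenvalues (sorted descending),
#' squared radius of gyration, asphericity, acylindricity, relative shape
#' anisotropy `kappa2`, and the ratio of object volume (in voxels) to the
#' volume of a sphere of radius `Rg`; intensity summaries (`mean_Id`,
#' `max_Id`) are carried over from detection. Note that for a true solid ball
#' `Rg^2 = 3 R^2 / 5`, so `sphere_ratio` of a perfect ball is a constant
#' `(5/3)^{3/2}`, not 1 — the literal ratio as named is reported.
#'
#' All coordinates are in voxel units; at a single acquisition resolution the
#' physical scale is a constant factor absorbed by the classifier.
#'
#' @param candidates Candidate tibble from [extract_candidates()] /
#'   [filter_by_intensity()] (needs the `voxels` list-column).
#' @return The input tibble with the [feature_columns()] appended
#'   (`voxels` retained).
#' @export
shape_features <- function(candidates) {
  if (!"voxels" %in% names(candidates)) {
    stop("candidates must carry a `voxels` list-column", call. = FALSE)
  }
  if (nrow(candidates) == 0L) {
    feats <- tibble::as_tibble(setNames(
      rep(list(numeric()), 8L),
      setdiff(feature_columns(), c("mean_Id", "max_Id"))
    ))
    return(dplyr::bind_cols(candidates, feats[0, ]))
  }
  feats <- purrr::map_dfr(candidates$voxels, shape_features_one)
  dplyr::bind_cols(
    dplyr::select(candidates, -dplyr::any_of(names(feats))),
    feats
  )
}
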