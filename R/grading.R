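#' Image-level NPDR severity grade
#'
#' Grades an image from its detected lesion counts, restricted to the lesion
#' types this system detects (microaneurysms, hemorrhages, hard exudates):
#' no lesions at all is `no_dr`; microaneurysms only is `mild`; any
#' hemorrhage or exudate is `moderate`; `severe` requires extensive
#' hemorrhages, operationalized by the 4-2-1 clause as more than 20
#' hemorrhages in each of the four quadrants (venous beading and IRMA, the
#' other 4-2-1 components, are not detected and cannot contribute).
#'
#' @param n_ma,n_hem,n_exu Non-negative lesion counts.
#' @param quadrant_hem Length-4 vector of per-quadrant hemorrhage counts
#'   (quadrants about the macula center, or the image center as fallback);
#'   defaults to all hemorrhages in one quadrant when omitted.
#' @return A `grading_result` list: `grade` (factor level among
#'   `no_dr < mild < moderate < severe`), `counts`, `quadrant_hem`.
#' @export
grade_npdr <- function(n_ma, n_hem, n_exu, quadrant_hem = NULL) {
  stopifnot(n_ma >= 0, n_hem >= 0, n_exu >= 0)
  if (is.null(quadrant_hem)) quadrant_hem <- c(n_hem, 0, 0, 0)
  stopifnot(length(quadrant_hem) == 4, all(quadrant_hem >= 0),
            sum(quadrant_hem) == n_hem)
  lv <- c("no_dr", "mild", "moderate", "severe")
  grade <-
    if (n_ma == 0 && n_hem == 0 && n_exu == 0) "no_dr"
    else if (all(quadrant_hem > 20)) "severe"
    else if (n_hem > 0 || n_exu > 0) "moderate"
    else "mild"
  structure(list(grade = factor(grade, levels = lv, ordered = TRUE),
                 counts = c(n_ma = n_ma, n_hem = n_hem, n_exu = n_exu),
                 quadrant_hem = quadrant_hem),
            class = "grading_result")
}

#' Per-quadrant hemorrhage counts
#'
#' Quadrants are delimited by the horizontal and vertical lines through the
#' given center (the macula when located, else the image center).
#'
#' @param centroids n x 2 matrix of hemorrhage (row, col) centroids.
#' @param center Quadrant origin (row, col).
#' @return Integer vector of length 4 (upper-left, upper-right, lower-left,
#'   lower-right).
#' @export
quadrant_counts <- function(centroids, center) {
  if (is.null(centroids) || !nrow(centroids)) return(c(0L, 0L, 0L, 0L))
  up <- centroids[, 1] <= center[1]
  left <- centroids[, 2] <= center[2]
  c(sum(up & left), sum(up & !left), sum(!up & left), sum(!up & !left))
}
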