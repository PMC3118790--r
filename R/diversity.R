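# Diversity and abundance indices of the station photo-quadrats, computed
# from the species-sediment percent-cover matrix.

#' Names of the eight biotic response columns
#'
#' Species density (d), overall abundance (A) and its base-10 log, Simpson
#' diversity (D) and its base-10 log, Shannon index on image fractions (H),
#' Log10(H + 1), and modified Pielou evenness (mJ).
#' @return Character vector of 8 names.
#' @export
response_names <- function() {
  c("d", "A", "LogA", "D", "LogD", "H", "LogH1", "mJ")
}

#' Diversity and abundance indices of one quadrat
#'
#' From the percent covers of one photograph:
#' \describe{
#'   \item{S}{species richness: number of biotic variables with cover > 0.}
#'   \item{d}{species density, S / quadrat area (per square meter).}
#'   \item{A}{overall abundance: sum of biotic percent covers (may exceed
#'     100 when canopies overlap).}
#'   \item{D}{Simpson diversity, 1 - sum((a_i / A)^2) over biotic covers.}
#'   \item{H}{Shannon index applied to image fractions f_i = cover% / 100 of
#'     the present biotic variables: -sum(f_i log f_i). Note this is the
#'     literal image-fraction form, not abundance-normalized, so it is not
#'     scale-free: doubling all covers changes H.}
#'   \item{mJ}{modified Pielou evenness, H / log(S + 1); 0 when S = 0.}
#' }
#' Log transforms are base 10; LogH1 is log10(H + 1). Zero-abundance
#' conventions: when A = 0, D, H and mJ are 0; log10 of a non-positive D or A
#' is reported as 0.
#'
#' @param q named numeric vector (or one-row data.frame) of percent covers.
#' @param quadrat_area quadrat footprint, square meters (default 0.16).
#' @param biotic names of the biotic cover variables (default the standard
#'   12-taxon pool).
#' @return Named list with S, d, A, LogA, D, LogD, H, LogH1, mJ.
#' @export
#' @examples
#' q <- setNames(rep(0, 12), benthic_species_pool())
#' q[c("Laminaria", "Fucus")] <- 30
#' compute_indices(q)$D   # 0.5: two equally abundant taxa
compute_indices <- function(q, quadrat_area = 0.16,
                            biotic = benthic_species_pool()) {
  if (is.data.frame(q)) q <- unlist(q[intersect(names(q), c(biotic, names(q)))])
  q <- q[!is.na(suppressWarnings(as.numeric(q)))]
  covers <- as.numeric(q[intersect(biotic, names(q))])
  if (length(covers) == 0) stop("no biotic cover values found", call. = FALSE)
  if (any(covers < 0)) stop("covers must be non-negative", call. = FALSE)

  a <- covers[covers > 0]
  S <- length(a)
  A <- sum(a)
  d <- S / quadrat_area
  if (A > 0) {
    D <- 1 - sum((a / A)^2)
    f <- a / 100
    H <- -sum(f * log(f))
  } else {
    D <- 0; H <- 0
  }
  mJ <- if (S > 0) H / log(S + 1) else 0
  list(S = S, d = d, A = A,
       LogA = if (A > 0) log10(A) else 0,
       D = D,
       LogD = if (D > 0) log10(D) else 0,
       H = H, LogH1 = log10(H + 1), mJ = mJ)
}

#' Biotic index table for a survey
#'
#' One row per station with the eight response columns in
#' [response_names()] order.
#'
#' @param quadrats data.frame from [generate_quadrats()] (or a real-survey
#'   cover table): `station_id` plus cover columns.
#' @inheritParams compute_indices
#' @return Data.frame: `station_id` and 8 response columns.
#' @export
index_table <- function(quadrats, quadrat_area = 0.16,
                        biotic = benthic_species_pool()) {
  rows <- lapply(seq_len(nrow(quadrats)), function(i) {
    ix <- compute_indices(unlist(quadrats[i, intersect(biotic, names(quadrats))]),
                          quadrat_area = quadrat_area, biotic = biotic)
    as.data.frame(ix[response_names()])
  })
  out <- cbind(data.frame(station_id = quadrats$station_id,
                          stringsAsFactors = FALSE),
               do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Pairwise correlations among the biotic responses
#'
#' Pearson and Spearman coefficients with two-sided p-values for every pair
#' of response columns.
#'
#' @param indices table from [index_table()].
#' @param cols columns to correlate (default the 8 responses).
#' @return List of matrices: `pearson`, `pearson_p`, `spearman`,
#'   `spearman_p`.
#' @export
response_correlations <- function(indices, cols = response_names()) {
  x <- as.matrix(indices[cols])
  p <- length(cols)
  out <- list(pearson = diag(p), pearson_p = matrix(0, p, p),
              spearman = diag(p), spearman_p = matrix(0, p, p))
  for (m in names(out)) dimnames(out[[m]]) <- list(cols, cols)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    pe <- suppressWarnings(cor.test(x[, i], x[, j], method = "pearson"))
    sp <- suppressWarnings(cor.test(x[, i], x[, j], method = "spearman",
                                    exact = FALSE))
    out$pearson[i, j] <- unname(pe$estimate)
    out$pearson_p[i, j] <- pe$p.value
    out$spearman[i, j] <- unname(sp$estimate)
    out$spearman_p[i, j] <- sp$p.value
  }
  out
}
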