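#' Grantham physicochemical distances between amino acids
#'
#' The Grantham (1974) distance combines side-chain composition (c),
#' polarity (p) and molecular volume (v) into
#' \deqn{D_{ij} = \rho\,[\alpha (c_i-c_j)^2 + \beta (p_i-p_j)^2 +
#'   \gamma (v_i-v_j)^2]^{1/2}}
#' with \eqn{\alpha = 1.833}, \eqn{\beta = 0.1018}, \eqn{\gamma = 0.000399}
#' and \eqn{\rho} scaling the mean over all pairs to 100. Distances range
#' from 5 (Leu/Ile) to 215 (Cys/Trp); the larger the value, the more radical
#' the replacement.
#'
#' `granthamDistance()` returns the distance as published in the 1974 matrix,
#' which is the form used throughout the field (and in the catalog's
#' annotations). `granthamFormula()` recomputes the distance from the
#' embedded c/p/v constants; for a handful of pairs the published matrix
#' differs from the recomputation by 1 unit because of rounding in the
#' original publication (e.g. Leu/Met computes 14.3 but is published as 15;
#' Asp/Trp is the single larger outlier, published 181 vs 190.6 computed),
#' so the matrix is authoritative and the formula is kept as a cross-check.
#'
#' @param aa1,aa2 one-letter amino-acid codes (standard 20).
#' @param rounded logical; round the formula value half-up to an integer.
#' @return numeric distance; 0 for identical residues.
#' @examples
#' granthamDistance("K", "R")  # 26
#' granthamDistance("D", "E")  # 45
#' @export
granthamDistance <- function(aa1, aa2) {
  i <- .aa_index(aa1); j <- .aa_index(aa2)
  .grantham_matrix[cbind(i, j)]
}

#' @rdname granthamDistance
#' @export
granthamFormula <- function(aa1, aa2, rounded = TRUE) {
  i <- .aa_index(aa1); j <- .aa_index(aa2)
  k <- .grantham_constants
  d <- k$rho * sqrt(k$alpha * (k$c[i] - k$c[j])^2 +
                    k$beta  * (k$p[i] - k$p[j])^2 +
                    k$gamma * (k$v[i] - k$v[j])^2)
  d <- unname(d)
  if (rounded) floor(d + 0.5) else d
}

.aa_order <- c("S","R","L","P","T","A","V","G","I","F",
               "Y","C","H","Q","N","K","D","E","M","W")

.aa_index <- function(aa) {
  aa <- toupper(as.character(aa))
  i <- match(aa, .aa_order)
  if (anyNA(i))
    stop("not a standard amino acid: ", paste(aa[is.na(i)], collapse = ", "))
  i
}

# side-chain composition, polarity and volume (Grantham 1974, Table 1)
.grantham_constants <- list(
  c = setNames(c(1.42, 0.65, 0, 0.39, 0.71, 0, 0, 0.74, 0, 0,
                 0.20, 2.75, 0.58, 0.89, 1.33, 0.33, 1.38, 0.92, 0, 0.13), .aa_order),
  p = setNames(c(9.2, 10.5, 4.9, 8.0, 8.6, 8.1, 5.9, 9.0, 5.2, 5.2,
                 6.2, 5.5, 10.4, 10.5, 11.6, 11.3, 13.0, 12.3, 5.7, 5.4), .aa_order),
  v = setNames(c(32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132,
                 136, 55, 96, 85, 56, 119, 54, 83, 105, 170), .aa_order),
  alpha = 1.833, beta = 0.1018, gamma = 0.000399, rho = 50.723
)

# published 1974 distance matrix, row order as .aa_order (upper triangle)
.grantham_matrix <- local({
  upper <- list(
    S = c(R=110,L=145,P=74,T=58,A=99,V=124,G=56,I=142,F=155,Y=144,C=112,H=89,
          Q=68,N=46,K=121,D=65,E=80,M=135,W=177),
    R = c(L=102,P=103,T=71,A=112,V=96,G=125,I=97,F=97,Y=77,C=180,H=29,Q=43,
          N=86,K=26,D=96,E=54,M=91,W=101),
    L = c(P=98,T=92,A=96,V=32,G=138,I=5,F=22,Y=36,C=198,H=99,Q=113,N=153,
          K=107,D=172,E=138,M=15,W=61),
    P = c(T=38,A=27,V=68,G=42,I=95,F=114,Y=110,C=169,H=77,Q=76,N=91,K=103,
          D=108,E=93,M=87,W=147),
    T = c(A=58,V=69,G=59,I=89,F=103,Y=92,C=149,H=47,Q=42,N=65,K=78,D=85,
          E=65,M=81,W=128),
    A = c(V=64,G=60,I=94,F=113,Y=112,C=195,H=86,Q=91,N=111,K=106,D=126,
          E=107,M=84,W=148),
    V = c(G=109,I=29,F=50,Y=55,C=192,H=84,Q=96,N=133,K=97,D=152,E=121,M=21,W=88),
    G = c(I=135,F=153,Y=147,C=159,H=98,Q=87,N=80,K=127,D=94,E=98,M=127,W=184),
    I = c(F=21,Y=33,C=198,H=94,Q=109,N=149,K=102,D=168,E=134,M=10,W=61),
    F = c(Y=22,C=205,H=100,Q=116,N=158,K=102,D=177,E=140,M=28,W=40),
    Y = c(C=194,H=83,Q=99,N=143,K=85,D=160,E=122,M=36,W=37),
    C = c(H=174,Q=154,N=139,K=202,D=154,E=170,M=196,W=215),
    H = c(Q=24,N=68,K=32,D=81,E=40,M=87,W=115),
    Q = c(N=46,K=53,D=61,E=29,M=101,W=130),
    N = c(K=94,D=23,E=42,M=142,W=174),
    K = c(D=101,E=56,M=95,W=110),
    D = c(E=45,M=160,W=181),
    E = c(M=126,W=152),
    M = c(W=67))
  m <- matrix(0, 20, 20, dimnames = list(.aa_order, .aa_order))
  for (a in names(upper)) for (b in names(upper[[a]])) {
    m[a, b] <- upper[[a]][[b]]
    m[b, a] <- upper[[a]][[b]]
  }
  m
})
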