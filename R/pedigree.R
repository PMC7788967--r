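#' Read and sort a pedigree
#'
#' Reads a three-column pedigree (animal, sire, dam; 0 = unknown) from a
#' whitespace- or comma-separated file with an optional header, adds
#' parents that never appear as animals as founders (with a message),
#' checks for duplicates and cycles, and sorts it so every parent
#' precedes its offspring.
#'
#' @param path Path to a pedigree file.
#' @return A `pedigree` object: data frame with columns `animal`,
#'   `sire`, `dam` (character ids, `"0"` = unknown) in topological
#'   order, with attribute `index` mapping ids to 1..n.
#' @export
read_pedigree <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  header <- grepl("animal|sire|dam|id", first, ignore.case = TRUE)
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  names(df)[1:3] <- c("animal", "sire", "dam")
  sort_pedigree(df[, 1:3])
}

#' Topologically sort and validate a pedigree
#'
#' @param ped Data frame or matrix with columns animal, sire, dam
#'   (0 or NA = unknown parent).
#' @return A sorted `pedigree` object (see [read_pedigree()]).
#' @export
sort_pedigree <- function(ped) {
  ped <- as.data.frame(ped, stringsAsFactors = FALSE)
  names(ped)[1:3] <- c("animal", "sire", "dam")
  a <- as.character(ped$animal)
  s <- as.character(ped$sire)
  d <- as.character(ped$dam)
  s[is.na(s)] <- "0"; d[is.na(d)] <- "0"
  if (anyDuplicated(a))
    stop("duplicate animal id: ", a[duplicated(a)][1])
  if (any(a == "0")) stop("animal id 0 is reserved for unknown parents")
  missing_par <- setdiff(union(s, d), c(a, "0"))
  if (length(missing_par) > 0L) {
    message(length(missing_par), " parent(s) without own record added as founders")
    a <- c(missing_par, a)
    s <- c(rep("0", length(missing_par)), s)
    d <- c(rep("0", length(missing_par)), d)
  }
  n <- length(a)
  id <- seq_len(n)
  names(id) <- a
  si <- ifelse(s == "0", 0L, id[s])
  di <- ifelse(d == "0", 0L, id[d])
  if (any(si == id) || any(di == id))
    stop("cycle in pedigree involving animal ", a[which(si == id | di == id)[1]])

  # Kahn topological sort over the parent -> offspring DAG
  indeg <- (si != 0L) + (di != 0L)
  children <- split(rep(id, 2L), c(si, di))
  children[["0"]] <- NULL
  queue <- id[indeg == 0L]
  ord <- integer(0)
  indeg_w <- indeg
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (ch in children[[as.character(v)]]) {
      indeg_w[ch] <- indeg_w[ch] - 1L
      if (indeg_w[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    on_cycle <- a[setdiff(id, ord)[1]]
    stop("cycle in pedigree involving animal ", on_cycle)
  }
  out <- data.frame(animal = a[ord], sire = s[ord], dam = d[ord],
                    stringsAsFactors = FALSE)
  idx <- seq_len(n)
  names(idx) <- out$animal
  structure(out, index = idx, class = c("pedigree", "data.frame"))
}

# integer parent indices (0 = unknown) of a sorted pedigree
ped_codes <- function(ped) {
  idx <- attr(ped, "index")
  if (is.null(idx)) stop("pedigree is not sorted; use sort_pedigree()")
  list(sire = ifelse(ped$sire == "0", 0L, as.integer(idx[ped$sire])),
       dam = ifelse(ped$dam == "0", 0L, as.integer(idx[ped$dam])),
       n = nrow(ped))
}

#' Inbreeding coefficients
#'
#' Computes the inbreeding coefficient of every animal in a sorted
#' pedigree with the Meuwissen and Luo algorithm (founders F = 0; F of
#' an animal equals half the additive relationship of its parents).
#'
#' @param ped A sorted `pedigree`.
#' @return Numeric vector of inbreeding coefficients in pedigree order,
#'   named by animal id.
#' @export
inbreeding <- function(ped) {
  pc <- ped_codes(ped)
  s <- pc$sire; d <- pc$dam; n <- pc$n
  f <- numeric(n)          # inbreeding
  D <- numeric(n)          # Mendelian-sampling variances
  AL <- numeric(n)         # path-coefficient workspace, reset as we go
  for (i in seq_len(n)) {
    D[i] <- 0.5 - 0.25 * ((if (s[i] > 0L) f[s[i]] else -1) +
                          (if (d[i] > 0L) f[d[i]] else -1))
    if (s[i] == 0L || d[i] == 0L) next   # F = 0 with an unknown parent
    # trace the ancestors of i in decreasing index order (parents always
    # precede offspring), accumulating path coefficients; the diagonal
    # a_ii = sum AL_j^2 D_j over i and its ancestors, and F_i = a_ii - 1
    AL[i] <- 1
    active <- i
    fi <- -1
    while (length(active) > 0L) {
      j <- max(active)
      active <- active[active != j]
      if (s[j] > 0L) {
        if (AL[s[j]] == 0) active <- c(active, s[j])
        AL[s[j]] <- AL[s[j]] + 0.5 * AL[j]
      }
      if (d[j] > 0L) {
        if (AL[d[j]] == 0) active <- c(active, d[j])
        AL[d[j]] <- AL[d[j]] + 0.5 * AL[j]
      }
      fi <- fi + AL[j]^2 * D[j]
      AL[j] <- 0
    }
    f[i] <- fi
  }
  names(f) <- ped$animal
  f
}

# Mendelian-sampling variances given inbreeding (vector F in ped order)
mendelian_variance <- function(ped, f = inbreeding(ped)) {
  pc <- ped_codes(ped)
  0.5 - 0.25 * (ifelse(pc$sire > 0L, f[pc$sire], -1) +
                ifelse(pc$dam > 0L, f[pc$dam], -1))
}

#' Numerator relationship matrix (tabular method)
#'
#' Builds the dense additive relationship matrix A by the tabular
#' method.  Intended for oracle checks and small pedigrees; the mixed
#' model uses the sparse inverse from [a_inverse()] instead.
#'
#' @param ped A sorted `pedigree`.
#' @return Dense symmetric matrix with `diag(A) = 1 + F`.
#' @export
make_A <- function(ped) {
  pc <- ped_codes(ped)
  s <- pc$sire; d <- pc$dam; n <- pc$n
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    A[i, i] <- 1 + 0.5 * (if (s[i] > 0L && d[i] > 0L) A[s[i], d[i]] else 0)
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (s[i] > 0L) A[j, s[i]] else 0) +
                    (if (d[i] > 0L) A[j, d[i]] else 0))
      A[j, i] <- A[i, j] <- aij
    }
  }
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembles A-inverse directly from the pedigree by Henderson's rules,
#' with Mendelian-sampling variances adjusted for parental inbreeding
#' (Meuwissen-Luo F).  Set `use_inbreeding = FALSE` to reproduce the
#' classical rules that ignore inbreeding.
#'
#' @param ped A sorted `pedigree`.
#' @param use_inbreeding Account for inbreeding in the
#'   Mendelian-sampling variances (default TRUE).
#' @return List of class `a_inverse` with elements `Ainv` (sparse
#'   symmetric [Matrix::dsCMatrix-class]), `F` (inbreeding
#'   coefficients), `log_det_A` (log-determinant of A) and `animals`.
#' @export
a_inverse <- function(ped, use_inbreeding = TRUE) {
  pc <- ped_codes(ped)
  s <- pc$sire; d <- pc$dam; n <- pc$n
  f <- if (use_inbreeding) inbreeding(ped) else numeric(n)
  m <- 0.5 - 0.25 * (ifelse(s > 0L, f[pmax(s, 1L)], -1) +
                     ifelse(d > 0L, f[pmax(d, 1L)], -1))
  alpha <- 1 / m
  # Henderson's rules as vectorized triplets (duplicates are summed)
  ks <- which(s > 0L); kd <- which(d > 0L); kb <- which(s > 0L & d > 0L)
  i_all <- seq_len(n)
  ii <- c(i_all, ks, s[ks], kd, d[kd], s[ks], d[kd], s[kb], d[kb])
  jj <- c(i_all, s[ks], ks, d[kd], kd, s[ks], d[kd], d[kb], s[kb])
  xx <- c(alpha,
          -alpha[ks] / 2, -alpha[ks] / 2, -alpha[kd] / 2, -alpha[kd] / 2,
          alpha[ks] / 4, alpha[kd] / 4, alpha[kb] / 4, alpha[kb] / 4)
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  Ainv <- Matrix::forceSymmetric((Ainv + Matrix::t(Ainv)) / 2)
  structure(list(Ainv = Ainv, F = f, log_det_A = sum(log(m)),
                 animals = ped$animal),
            class = "a_inverse")
}

#' Write a pedigree file
#'
#' @param ped A `pedigree`.
#' @param path Output path (comma-separated with header).
#' @return The path, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.table(as.data.frame(ped)[, c("animal", "sire", "dam")], path,
                     sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
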