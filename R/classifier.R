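# Internal sparse-feature / one-vs-rest linear model machinery shared by the
# pipeline phases. Feature instances are character vectors (repeats = counts).

feature_matrix <- function(feat_list, vocab = NULL) {
  if (is.null(vocab)) {
    vocab <- sort(unique(unlist(feat_list, use.names = FALSE)))
  }
  n <- length(feat_list)
  lens <- lengths(feat_list)
  ii <- rep(seq_len(n), lens)
  jj <- match(unlist(feat_list, use.names = FALSE), vocab)
  keep <- !is.na(jj)
  # at least two columns so glmnet accepts the design
  m <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep],
                            x = rep(1, sum(keep)),
                            dims = c(n, max(length(vocab), 2L)))
  list(m = m, vocab = vocab)
}

fit_ovr <- function(feat_list, labels, label_space, lambda = 1e-4) {
  fm <- feature_matrix(feat_list)
  lam_path <- sort(unique(c(1, 0.1, 0.01, 1e-3, lambda)), decreasing = TRUE)
  fits <- lapply(label_space, function(lb) {
    y <- as.integer(labels == lb)
    if (sum(y) == 0) return(list(kind = "never"))
    if (sum(y) == length(y)) return(list(kind = "always"))
    # glmnet warns about very small classes on tiny fixtures; harmless here
    fit <- suppressWarnings(
      glmnet::glmnet(fm$m, y, family = "binomial", alpha = 0,
                     lambda = lam_path, standardize = FALSE))
    co <- glmnet::coef.glmnet(fit, s = lambda, exact = FALSE)
    list(kind = "model", a0 = co[1, 1], beta = co[-1, 1, drop = TRUE])
  })
  structure(list(fits = fits, label_space = label_space, vocab = fm$vocab,
                 lambda = lambda),
            class = "ovr_model")
}

predict_ovr <- function(model, feat_list, scores = FALSE) {
  fm <- feature_matrix(feat_list, vocab = model$vocab)
  n <- length(feat_list)
  sc <- vapply(model$fits, function(f) {
    switch(f$kind,
           never = rep(-Inf, n),
           always = rep(Inf, n),
           model = as.numeric(fm$m %*% f$beta) + f$a0)
  }, numeric(n))
  if (n == 1) sc <- matrix(sc, nrow = 1)
  colnames(sc) <- model$label_space
  if (scores) return(sc)
  # argmax with deterministic tie-break by label order
  model$label_space[apply(sc, 1, which.max)]
}

#' @export
tidy.ovr_model <- function(x, ...) {
  purrr::map2_dfr(x$fits, x$label_space, function(f, lb) {
    if (f$kind != "model") return(NULL)
    nz <- which(f$beta != 0)
    tibble(class = lb, term = x$vocab[nz], estimate = unname(f$beta[nz]))
  })
}
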