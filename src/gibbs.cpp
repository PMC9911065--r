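// Gibbs sampler for the multivariate Gaussian mixed model
//
//   y_i = B' x_i + u_{line(i)} + w_{block(i)} + e_i
//   u_l ~ N(0, G_line),  w_b ~ N(0, G_block),  e_i ~ N(0, R)
//
// with conjugate full conditionals: multivariate normal for the fixed-effect
// coefficients and the random-effect vectors, inverse-Wishart for the three
// covariance matrices. Priors: vec(B) ~ N(0, v_beta I); G_line, G_block and
// R ~ IW(nu0, S0) with S0 a diagonal matrix of phenotypic variances.
//
// Randomness comes from R's RNG (norm_rand / rchisq under RNGScope), so a
// set.seed() call on the R side makes the whole chain reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// draw x ~ N(m, P^{-1}) from precision P via upper Cholesky P = U'U
static vec rmvn_prec(const vec& m, const mat& P) {
  mat U = chol(P);            // upper triangular
  vec z(m.n_elem);
  for (uword i = 0; i < z.n_elem; ++i) z(i) = norm_rand();
  return m + solve(trimatu(U), z);
}

// Wishart(df, Sigma) via Bartlett decomposition; df > d-1
static mat rwishart(double df, const mat& Sigma) {
  uword d = Sigma.n_rows;
  mat A(d, d, fill::zeros);
  for (uword i = 0; i < d; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - (double)i));
    for (uword j = 0; j < i; ++j) A(i, j) = norm_rand();
  }
  mat L = chol(Sigma, "lower");
  mat LA = L * A;
  return LA * LA.t();
}

// inverse-Wishart(df, S): invert a Wishart(df, S^{-1}) draw
static mat rinvwishart_cpp(double df, const mat& S) {
  mat W = rwishart(df, inv_sympd(symmatu(S)));
  return inv_sympd(symmatu(W));
}

// [[Rcpp::export(name = ".gibbs_mmm")]]
Rcpp::List gibbs_mmm(const arma::mat& Y,      // N x d responses
                     const arma::mat& X,      // N x p fixed design
                     const arma::uvec& line,  // 0-based line index, length N
                     const arma::uvec& block, // 0-based block index
                     int n_lines, int n_blocks,
                     double nu0, const arma::mat& S0,
                     double v_beta,
                     int n_iter, int burnin, int thin) {
  const uword N = Y.n_rows, d = Y.n_cols, p = X.n_cols;
  const uword L = (uword)n_lines, Bn = (uword)n_blocks;

  if (burnin >= n_iter) Rcpp::stop("burnin must be smaller than n_iter");
  const int n_keep = (n_iter - burnin) / thin;
  if (n_keep < 1) Rcpp::stop("no samples would be stored");

  // replicate counts per level; levels sharing a count share the conditional
  // precision, so they can be updated with a single Cholesky factor
  vec cnt_line(L, fill::zeros), cnt_block(Bn, fill::zeros);
  for (uword i = 0; i < N; ++i) {
    cnt_line(line(i)) += 1.0;
    cnt_block(block(i)) += 1.0;
  }
  vec uniq_line = unique(cnt_line), uniq_block = unique(cnt_block);
  std::vector<uvec> grp_line, grp_block;
  for (uword k = 0; k < uniq_line.n_elem; ++k)
    grp_line.push_back(find(cnt_line == uniq_line(k)));
  for (uword k = 0; k < uniq_block.n_elem; ++k)
    grp_block.push_back(find(cnt_block == uniq_block(k)));

  const mat XtX = X.t() * X;

  // state
  mat Bcoef(p, d, fill::zeros);
  mat U(L, d, fill::zeros), W(Bn, d, fill::zeros);
  mat Gline = S0, Gblock = S0, Rres = S0;

  cube keep_line(d, d, n_keep), keep_block(d, d, n_keep), keep_res(d, d, n_keep);
  cube keep_beta(p, d, n_keep);

  Rcpp::RNGScope scope;

  int stored = 0;
  for (int it = 0; it < n_iter; ++it) {
   try {
    mat Rinv = inv_sympd(symmatu(Rres));

    // --- fixed effects: vec(B) (column-major, p*d) ---
    {
      mat Ytil = Y - U.rows(line) - W.rows(block);
      mat A = kron(Rinv, XtX);
      A.diag() += 1.0 / v_beta;
      mat RHS = X.t() * Ytil * Rinv;        // p x d
      vec b = vectorise(RHS);
      mat Uc = chol(A);
      vec mean = solve(trimatu(Uc), solve(trimatl(Uc.t()), b));
      vec theta = rmvn_prec(mean, A);
      Bcoef = reshape(theta, p, d);
    }

    const mat XB = X * Bcoef;

    // --- line effects (grouped by replicate count) ---
    {
      mat Ginv = inv_sympd(symmatu(Gline));
      mat Ytil = Y - XB - W.rows(block);
      mat Ssum(d, L, fill::zeros);
      for (uword i = 0; i < N; ++i) Ssum.col(line(i)) += Ytil.row(i).t();
      mat RinvS = Rinv * Ssum;
      for (uword k = 0; k < grp_line.size(); ++k) {
        const uvec& idx = grp_line[k];
        double c = uniq_line(k);
        mat Z(d, idx.n_elem);
        for (uword e = 0; e < Z.n_elem; ++e) Z(e) = norm_rand();
        if (c == 0.0) { // unobserved level: draw from the prior
          U.rows(idx) = (chol(symmatu(Gline), "lower") * Z).t();
          continue;
        }
        mat P = c * Rinv + Ginv;
        mat Uc = chol(P);
        mat mean = solve(trimatu(Uc), solve(trimatl(Uc.t()), RinvS.cols(idx)));
        U.rows(idx) = (mean + solve(trimatu(Uc), Z)).t();
      }
    }

    // --- block effects (grouped by replicate count) ---
    {
      mat Ginv = inv_sympd(symmatu(Gblock));
      mat Ytil = Y - XB - U.rows(line);
      mat Ssum(d, Bn, fill::zeros);
      for (uword i = 0; i < N; ++i) Ssum.col(block(i)) += Ytil.row(i).t();
      mat RinvS = Rinv * Ssum;
      for (uword k = 0; k < grp_block.size(); ++k) {
        const uvec& idx = grp_block[k];
        double c = uniq_block(k);
        mat Z(d, idx.n_elem);
        for (uword e = 0; e < Z.n_elem; ++e) Z(e) = norm_rand();
        if (c == 0.0) {
          W.rows(idx) = (chol(symmatu(Gblock), "lower") * Z).t();
          continue;
        }
        mat P = c * Rinv + Ginv;
        mat Uc = chol(P);
        mat mean = solve(trimatu(Uc), solve(trimatl(Uc.t()), RinvS.cols(idx)));
        W.rows(idx) = (mean + solve(trimatu(Uc), Z)).t();
      }
    }

    // --- covariance matrices (inverse-Wishart full conditionals) ---
    Gline = rinvwishart_cpp(nu0 + (double)L, symmatu(S0 + U.t() * U));
    Gblock = rinvwishart_cpp(nu0 + (double)Bn, symmatu(S0 + W.t() * W));
    {
      mat E = Y - XB - U.rows(line) - W.rows(block);
      Rres = rinvwishart_cpp(nu0 + (double)N, symmatu(S0 + E.t() * E));
    }

    if (it >= burnin && (it - burnin) % thin == 0 && stored < n_keep) {
      keep_line.slice(stored) = Gline;
      keep_block.slice(stored) = Gblock;
      keep_res.slice(stored) = Rres;
      keep_beta.slice(stored) = Bcoef;
      ++stored;
    }
   } catch (std::exception& e) {
     Rcpp::stop("conditional covariance not positive-definite at iteration %d: %s",
                it + 1, e.what());
   }
  }

  return Rcpp::List::create(
    Rcpp::Named("line") = keep_line,
    Rcpp::Named("block") = keep_block,
    Rcpp::Named("residual") = keep_res,
    Rcpp::Named("beta") = keep_beta,
    Rcpp::Named("n_stored") = stored);
}

// [[Rcpp::export(name = ".rinvwishart")]]
arma::mat rinvwishart_export(double df, const arma::mat& S) {
  if (df <= S.n_rows - 1)
    Rcpp::stop("inverse-Wishart requires df > d - 1");
  Rcpp::RNGScope scope;
  return rinvwishart_cpp(df, S);
}
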