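// Iteratively reweighted least squares for logistic regression, plus a
// batched permutation scan that refits every window's global test under
// permuted case-control labels. Kept in C++ because a permutation run
// performs hundreds of thousands of fits.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double bern_loglik(const arma::vec& y, const arma::vec& eta) {
    double ll = 0.0;
    for (arma::uword i = 0; i < y.n_elem; ++i) {
        double e = eta[i];
        // log(1 + exp(e)) computed stably
        double lse = (e > 0) ? e + std::log1p(std::exp(-e))
                             : std::log1p(std::exp(e));
        ll += y[i] * e - lse;
    }
    return ll;
}

struct IrlsFit {
    arma::vec beta;
    arma::vec se;
    double loglik;
    int iter;
    bool converged;
};

static IrlsFit irls(const arma::mat& X, const arma::vec& y,
                    double tol, int maxit,
                    const arma::vec* start = nullptr) {
    const arma::uword p = X.n_cols;
    arma::vec beta(p, arma::fill::zeros);
    if (start != nullptr) beta = *start;
    arma::vec eta = X * beta;
    double ll = bern_loglik(y, eta);
    bool converged = false;
    int it = 0;
    arma::mat XtWX(p, p);
    for (it = 1; it <= maxit; ++it) {
        arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
        mu.clamp(1e-12, 1.0 - 1e-12);
        arma::vec w = mu % (1.0 - mu);
        XtWX = X.t() * (X.each_col() % w);
        arma::vec score = X.t() * (y - mu);
        arma::vec step;
        bool ok = arma::solve(step, XtWX, score,
                              arma::solve_opts::likely_sympd +
                              arma::solve_opts::no_approx);
        if (!ok) { converged = false; break; }
        // Newton step with halving if the log-likelihood would decrease
        double llNew = ll;
        arma::vec betaNew = beta;
        double fac = 1.0;
        for (int h = 0; h < 25; ++h) {
            betaNew = beta + fac * step;
            arma::vec etaNew = X * betaNew;
            llNew = bern_loglik(y, etaNew);
            if (llNew >= ll - 1e-12) { eta = etaNew; break; }
            fac *= 0.5;
        }
        double dll = llNew - ll;
        beta = betaNew;
        ll = llNew;
        if (arma::abs(beta).max() > 30.0) {   // quasi-complete separation
            converged = false;
            break;
        }
        if (std::fabs(dll) < tol) { converged = true; break; }
    }
    // observed-information standard errors at the final estimate
    arma::vec mu = 1.0 / (1.0 + arma::exp(-(X * beta)));
    mu.clamp(1e-12, 1.0 - 1e-12);
    arma::vec w = mu % (1.0 - mu);
    XtWX = X.t() * (X.each_col() % w);
    arma::vec se(p);
    arma::mat cov;
    if (arma::inv_sympd(cov, XtWX))
        se = arma::sqrt(cov.diag());
    else
        se.fill(NA_REAL);
    IrlsFit out;
    out.beta = beta; out.se = se; out.loglik = ll;
    out.iter = it > maxit ? maxit : it; out.converged = converged;
    return out;
}

// [[Rcpp::export]]
List cpp_irls(const arma::mat& X, const arma::vec& y,
              double tol = 1e-8, int maxit = 50) {
    IrlsFit f = irls(X, y, tol, maxit);
    return List::create(
        Named("coefficients") = f.beta,
        Named("se") = f.se,
        Named("loglik") = f.loglik,
        Named("iter") = f.iter,
        Named("converged") = f.converged);
}

// Permutation scan: for each permuted label column of Y and each window's
// dosage-design block, likelihood-ratio p-value of the global haplotype
// test against the covariates-only model. Returns a B x W matrix of
// p-values (NA where a fit failed to converge).
// [[Rcpp::export]]
NumericMatrix cpp_perm_scan(const arma::mat& covX, List dosages,
                            const arma::mat& Y, IntegerVector df,
                            double tol = 1e-8, int maxit = 50) {
    const int B = Y.n_cols;
    const int W = dosages.size();
    NumericMatrix out(B, W);
    std::fill(out.begin(), out.end(), NA_REAL);

    std::vector<double> ll0(B);
    std::vector<bool> ok0(B);
    arma::mat beta0(covX.n_cols, B);
    for (int b = 0; b < B; ++b) {
        IrlsFit f0 = irls(covX, Y.col(b), tol, maxit);
        ll0[b] = f0.loglik;
        ok0[b] = f0.converged;
        beta0.col(b) = f0.beta;
    }
    for (int w = 0; w < W; ++w) {
        arma::mat D = as<arma::mat>(dosages[w]);
        arma::mat X = arma::join_rows(covX, D);
        for (int b = 0; b < B; ++b) {
            if (!ok0[b]) continue;
            // warm start at the null fit (dosage coefficients zero)
            arma::vec st(X.n_cols, arma::fill::zeros);
            st.head(covX.n_cols) = beta0.col(b);
            IrlsFit f1 = irls(X, Y.col(b), tol, maxit, &st);
            if (!f1.converged) continue;
            double stat = 2.0 * (f1.loglik - ll0[b]);
            if (stat < 0) stat = 0;
            out(b, w) = R::pchisq(stat, (double)df[w], 0, 0);
        }
        Rcpp::checkUserInterrupt();
    }
    return out;
}
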