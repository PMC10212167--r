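// Fused training step: forward pass, masked cross-entropy and full
// backward pass in one call, with single-precision internals.
//
// Keeping every intermediate feature map inside this translation unit
// avoids R-boundary copies and allocator churn, which dominate the run
// time of the layer-by-layer path; single precision halves the memory
// traffic of the convolution gathers on top. Parameters and gradients
// cross the boundary in double precision, so the optimizer state is
// unaffected. The double-precision layer primitives exported to R remain
// the reference implementation this kernel is tested against.
//
// Dropout masks are drawn on the R side (one C x B matrix per
// convolution, already scaled by 1/(1-rate)) so that all randomness
// flows from the master seed through R's RNG.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using arma::fmat;
using arma::fvec;

static fmat as_f(const Rcpp::NumericMatrix& x) {
    fmat out(x.nrow(), x.ncol());
    const double* src = x.begin();
    float* dst = out.memptr();
    for (R_xlen_t i = 0; i < x.size(); ++i)
        dst[i] = static_cast<float>(src[i]);
    return out;
}

static fvec as_fv(const Rcpp::NumericVector& x) {
    fvec out(x.size());
    for (R_xlen_t i = 0; i < x.size(); ++i)
        out[i] = static_cast<float>(x[i]);
    return out;
}

static Rcpp::NumericMatrix wrap_f(const fmat& x) {
    Rcpp::NumericMatrix out(x.n_rows, x.n_cols);
    const float* src = x.memptr();
    double* dst = out.begin();
    for (size_t i = 0; i < x.n_elem; ++i)
        dst[i] = static_cast<double>(src[i]);
    return out;
}

static Rcpp::NumericVector wrap_fv(const fvec& x) {
    Rcpp::NumericVector out(x.n_elem);
    for (size_t i = 0; i < x.n_elem; ++i)
        out[i] = static_cast<double>(x[i]);
    return out;
}

static void im2col_f(const fmat& X, int W, int B, int d, int K, fmat& cols) {
    const int C = X.n_rows;
    for (int i = 0; i < K; ++i) {
        const int off = d * i;
        for (int b = 0; b < B; ++b) {
            const int base = b * W;
            for (int t = 0; t < W; ++t) {
                float* dst = cols.colptr(base + t) + i * C;
                const int src = t - off;
                if (src >= 0)
                    std::memcpy(dst, X.colptr(base + src),
                                C * sizeof(float));
                else
                    std::memset(dst, 0, C * sizeof(float));
            }
        }
    }
}

static void col2im_f(const fmat& dcols, int C, int W, int B, int d, int K,
                     fmat& dX) {
    dX.zeros(C, static_cast<size_t>(W) * B);
    for (int i = 0; i < K; ++i) {
        const int off = d * i;
        for (int b = 0; b < B; ++b) {
            const int base = b * W;
            for (int t = off; t < W; ++t) {
                const float* src = dcols.colptr(base + t) + i * C;
                float* dst = dX.colptr(base + t - off);
                for (int c = 0; c < C; ++c)
                    dst[c] += src[c];
            }
        }
    }
}

// expand a C x B channel mask across the W positions of each window
static void apply_channel_mask(fmat& X, const fmat& mask, int W, int B) {
    for (int b = 0; b < B; ++b)
        for (int t = 0; t < W; ++t)
            X.col(b * W + t) %= mask.col(b);
}

struct ConvP {
    fmat V;      // direction, C_out x (C_in*K)
    fvec g;      // per-filter scale
    fvec b;      // bias
    fmat Wmat;   // effective weight g * V / ||V||
    fvec nr;     // row norms of V
};

static ConvP read_conv(const Rcpp::List& cv) {
    ConvP p;
    p.V = as_f(cv["V"]);
    p.g = as_fv(cv["g"]);
    p.b = as_fv(cv["b"]);
    p.nr = arma::sqrt(arma::sum(p.V % p.V, 1));
    p.Wmat = p.V.each_col() % (p.g / p.nr);
    return p;
}

// gradient of the weight-norm re-parameterization
static Rcpp::List conv_grad(const ConvP& p, const fmat& dW, const fvec& db) {
    fvec dg = arma::sum(dW % p.V, 1) / p.nr;
    fmat dV = dW.each_col() % (p.g / p.nr);
    dV -= p.V.each_col() % (p.g % dg / (p.nr % p.nr));
    return Rcpp::List::create(Rcpp::Named("V") = wrap_f(dV),
                              Rcpp::Named("g") = wrap_fv(dg),
                              Rcpp::Named("b") = wrap_fv(db));
}

// [[Rcpp::export]]
Rcpp::List tcn_train_step_cpp(Rcpp::List params, Rcpp::IntegerMatrix codes,
                              Rcpp::IntegerVector labels,
                              Rcpp::LogicalVector mask,
                              Rcpp::List dropout_masks,
                              Rcpp::IntegerVector dilations, int K,
                              int in_dim, int n_classes) {
    const int W = codes.nrow(), B = codes.ncol();
    const size_t n = static_cast<size_t>(W) * B;
    const int nblocks = dilations.size();

    Rcpp::List blocks = params["blocks"];
    Rcpp::List post = params["post"];

    // ---- forward ----
    fmat X(in_dim, n, arma::fill::zeros);
    for (size_t t = 0; t < n; ++t)
        X(codes[t], t) = 1.0f;

    std::vector<std::vector<ConvP> > cp(nblocks);
    std::vector<std::vector<fmat> > cols(nblocks), pre(nblocks);
    std::vector<fmat> x_in(nblocks), s_sum(nblocks);
    std::vector<fmat> projW(nblocks);
    std::vector<fvec> projb(nblocks);
    std::vector<bool> has_proj(nblocks, false);

    const bool use_dropout = dropout_masks.size() > 0;
    int mask_ix = 0;

    fmat h = X;
    for (int bi = 0; bi < nblocks; ++bi) {
        Rcpp::List blk = blocks[bi];
        Rcpp::List convs = blk["convs"];
        const int d = dilations[bi];
        x_in[bi] = h;
        cp[bi].resize(convs.size());
        cols[bi].resize(convs.size());
        pre[bi].resize(convs.size());
        for (int j = 0; j < convs.size(); ++j) {
            ConvP& p = cp[bi][j];
            p = read_conv(convs[j]);
            fmat& cl = cols[bi][j];
            cl.set_size(p.Wmat.n_cols, n);
            im2col_f(h, W, B, d, K, cl);
            fmat pr = p.Wmat * cl;
            pr.each_col() += p.b;
            pre[bi][j] = pr;
            h = arma::clamp(pr, 0.0f, arma::datum::inf);
            if (use_dropout) {
                fmat dm = as_f(dropout_masks[mask_ix++]);
                apply_channel_mask(h, dm, W, B);
            }
        }
        fmat skip;
        if (!Rf_isNull(blk["proj"])) {
            Rcpp::List proj = blk["proj"];
            projW[bi] = as_f(proj["W"]);
            projb[bi] = as_fv(proj["b"]);
            has_proj[bi] = true;
            skip = projW[bi] * x_in[bi];
            skip.each_col() += projb[bi];
        } else {
            skip = x_in[bi];
        }
        s_sum[bi] = skip + h;
        h = arma::clamp(s_sum[bi], 0.0f, arma::datum::inf);
    }
    fmat h_out = h;

    Rcpp::List p1 = post["conv1x1"], pout = post["out"];
    fmat W1 = as_f(p1["W"]);
    fvec b1 = as_fv(p1["b"]);
    fmat Wo = as_f(pout["W"]);
    fvec bo = as_fv(pout["b"]);

    fmat a1_pre = W1 * h_out;
    a1_pre.each_col() += b1;
    fmat a1 = arma::clamp(a1_pre, 0.0f, arma::datum::inf);
    fmat logits = Wo * a1;
    logits.each_col() += bo;

    // column softmax + masked cross-entropy (double accumulation)
    fmat probs = logits;
    double loss = 0.0;
    size_t nmask = 0;
    for (size_t t = 0; t < n; ++t) {
        fvec c = probs.col(t);
        const float mx = c.max();
        c = arma::exp(c - mx);
        c /= arma::accu(c);
        probs.col(t) = c;
        if (mask[t]) {
            ++nmask;
            const float p = std::max(c[labels[t]], 1e-12f);
            loss -= std::log(static_cast<double>(p));
        }
    }
    loss /= static_cast<double>(nmask);

    // ---- backward ----
    fmat dlogits = probs;
    for (size_t t = 0; t < n; ++t) {
        if (mask[t])
            dlogits(labels[t], t) -= 1.0f;
        else
            dlogits.col(t).zeros();
    }
    dlogits /= static_cast<float>(nmask);

    fmat dWo = dlogits * a1.t();
    fvec dbo = arma::sum(dlogits, 1);
    fmat da1 = Wo.t() * dlogits;
    da1 %= arma::conv_to<fmat>::from(a1_pre > 0);
    fmat dW1 = da1 * h_out.t();
    fvec db1 = arma::sum(da1, 1);
    fmat dh = W1.t() * da1;

    Rcpp::List gblocks(nblocks);
    fmat dX, dcols;
    for (int bi = nblocks - 1; bi >= 0; --bi) {
        const int d = dilations[bi];
        fmat ds = dh % arma::conv_to<fmat>::from(s_sum[bi] > 0);
        fmat dx_skip;
        Rcpp::RObject gproj(R_NilValue);   // RObject: GC-protected handle
        if (has_proj[bi]) {
            fmat dPW = ds * x_in[bi].t();
            fvec dPb = arma::sum(ds, 1);
            dx_skip = projW[bi].t() * ds;
            gproj = Rcpp::List::create(Rcpp::Named("W") = wrap_f(dPW),
                                       Rcpp::Named("b") = wrap_fv(dPb));
        } else {
            dx_skip = ds;
        }
        fmat dout = ds;
        const int nc = cp[bi].size();
        Rcpp::List gconvs(nc);
        for (int j = nc - 1; j >= 0; --j) {
            if (use_dropout) {
                fmat dm = as_f(dropout_masks[--mask_ix]);
                apply_channel_mask(dout, dm, W, B);
            }
            dout %= arma::conv_to<fmat>::from(pre[bi][j] > 0);
            const ConvP& p = cp[bi][j];
            fmat dW = dout * cols[bi][j].t();
            fvec db = arma::sum(dout, 1);
            gconvs[j] = conv_grad(p, dW, db);
            dcols = p.Wmat.t() * dout;
            const int Cin = (j == 0) ? x_in[bi].n_rows : p.Wmat.n_rows;
            col2im_f(dcols, Cin, W, B, d, K, dX);
            dout = dX;
        }
        gblocks[bi] = Rcpp::List::create(Rcpp::Named("convs") = gconvs,
                                         Rcpp::Named("proj") = gproj);
        dh = dx_skip + dout;
    }

    Rcpp::List gpost = Rcpp::List::create(
        Rcpp::Named("conv1x1") = Rcpp::List::create(
            Rcpp::Named("W") = wrap_f(dW1), Rcpp::Named("b") = wrap_fv(db1)),
        Rcpp::Named("out") = Rcpp::List::create(
            Rcpp::Named("W") = wrap_f(dWo), Rcpp::Named("b") = wrap_fv(dbo)));

    return Rcpp::List::create(
        Rcpp::Named("loss") = loss,
        Rcpp::Named("grads") = Rcpp::List::create(
            Rcpp::Named("blocks") = gblocks, Rcpp::Named("post") = gpost));
}
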