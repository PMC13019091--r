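// Minimal convolutional network for 4-way event classification:
// conv(k x k, C1) -> max-pool 2x2 -> conv(k x k, C2) -> max-pool 2x2 ->
// flatten -> fully connected -> 4-way softmax, cross-entropy loss,
// Adam updates.  All randomness (weight init, batch order) is supplied
// from R so training is deterministic given a seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::as;

static mat im2colCube(const cube& x, int k) {
    const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
    const int oh = H - k + 1, ow = W - k + 1;
    mat out(k * k * C, oh * ow);
    for (int j = 0; j < ow; ++j) {
        for (int i = 0; i < oh; ++i) {
            const int col = j * oh + i;
            int r = 0;
            for (int c = 0; c < C; ++c)
                for (int kj = 0; kj < k; ++kj)
                    for (int ki = 0; ki < k; ++ki)
                        out(r++, col) = x(i + ki, j + kj, c);
        }
    }
    return out;
}

static cube col2imCube(const mat& colsGrad, int H, int W, int C, int k) {
    const int oh = H - k + 1, ow = W - k + 1;
    cube g(H, W, C, fill::zeros);
    for (int j = 0; j < ow; ++j) {
        for (int i = 0; i < oh; ++i) {
            const int col = j * oh + i;
            int r = 0;
            for (int c = 0; c < C; ++c)
                for (int kj = 0; kj < k; ++kj)
                    for (int ki = 0; ki < k; ++ki)
                        g(i + ki, j + kj, c) += colsGrad(r++, col);
        }
    }
    return g;
}

// 2x2 max pool on activations stored as (channels x oh*ow), spatial
// column-major; windows that do not fit (odd edge) are cropped.
static mat maxPool(const mat& a, int oh, int ow, umat& argIdx) {
    const int C = a.n_rows, qh = oh / 2, qw = ow / 2;
    mat p(C, qh * qw);
    argIdx.set_size(C, qh * qw);
    for (int qj = 0; qj < qw; ++qj) {
        for (int qi = 0; qi < qh; ++qi) {
            const int qcol = qj * qh + qi;
            const int base[4] = {
                (2 * qi) + (2 * qj) * oh, (2 * qi + 1) + (2 * qj) * oh,
                (2 * qi) + (2 * qj + 1) * oh,
                (2 * qi + 1) + (2 * qj + 1) * oh };
            for (int c = 0; c < C; ++c) {
                double best = a(c, base[0]);
                int bi = base[0];
                for (int t = 1; t < 4; ++t) {
                    if (a(c, base[t]) > best) {
                        best = a(c, base[t]);
                        bi = base[t];
                    }
                }
                p(c, qcol) = best;
                argIdx(c, qcol) = bi;
            }
        }
    }
    return p;
}

struct Net {
    mat W1, W2, W3, W4;
    vec b1, b2, b3, b4;
    int k;
};

static Net unpack(const List& params) {
    Net n;
    n.W1 = as<mat>(params["W1"]); n.b1 = as<vec>(params["b1"]);
    n.W2 = as<mat>(params["W2"]); n.b2 = as<vec>(params["b2"]);
    n.W3 = as<mat>(params["W3"]); n.b3 = as<vec>(params["b3"]);
    n.W4 = as<mat>(params["W4"]); n.b4 = as<vec>(params["b4"]);
    n.k = (int) std::lround(std::sqrt((double) n.W1.n_cols));
    return n;
}

struct Cache {
    mat col1, z1, p1, col2, z2, p2;
    umat arg1, arg2;
    vec f, zh, h, prob;
    int o1, o2, q1, q2;
};

static double forwardImage(const Net& net, const mat& x, int y,
                           Cache& cc, bool wantLoss) {
    const int S = x.n_rows, k = net.k;
    const int C1 = net.W1.n_rows, C2 = net.W2.n_rows;
    cc.o1 = S - k + 1; cc.q1 = cc.o1 / 2;
    cube x1(const_cast<double*>(x.memptr()), S, S, 1, false, true);
    cc.col1 = im2colCube(x1, k);
    cc.z1 = net.W1 * cc.col1;
    cc.z1.each_col() += net.b1;
    mat a1 = clamp(cc.z1, 0.0, datum::inf);
    cc.p1 = maxPool(a1, cc.o1, cc.o1, cc.arg1);
    cube p1c(cc.q1, cc.q1, C1);
    for (int c = 0; c < C1; ++c)
        p1c.slice(c) = reshape(cc.p1.row(c), cc.q1, cc.q1);
    cc.o2 = cc.q1 - k + 1; cc.q2 = cc.o2 / 2;
    cc.col2 = im2colCube(p1c, k);
    cc.z2 = net.W2 * cc.col2;
    cc.z2.each_col() += net.b2;
    mat a2 = clamp(cc.z2, 0.0, datum::inf);
    cc.p2 = maxPool(a2, cc.o2, cc.o2, cc.arg2);
    cc.f = vectorise(cc.p2.t());   // channel-fastest? keep consistent
    cc.zh = net.W3 * cc.f + net.b3;
    cc.h = clamp(cc.zh, 0.0, datum::inf);
    vec u = net.W4 * cc.h + net.b4;
    u -= u.max();
    vec e = exp(u);
    cc.prob = e / accu(e);
    if (!wantLoss) return 0.0;
    return -std::log(std::max(cc.prob((uword) y), 1e-12));
}

struct Grads {
    mat W1, W2, W3, W4;
    vec b1, b2, b3, b4;
    void init(const Net& n) {
        W1.zeros(size(n.W1)); W2.zeros(size(n.W2));
        W3.zeros(size(n.W3)); W4.zeros(size(n.W4));
        b1.zeros(n.b1.n_elem); b2.zeros(n.b2.n_elem);
        b3.zeros(n.b3.n_elem); b4.zeros(n.b4.n_elem);
    }
};

static void backwardImage(const Net& net, const mat& x, int y,
                          const Cache& cc, Grads& g) {
    const int C1 = net.W1.n_rows, C2 = net.W2.n_rows, k = net.k;
    vec du = cc.prob;
    du((uword) y) -= 1.0;
    g.W4 += du * cc.h.t();
    g.b4 += du;
    vec dh = net.W4.t() * du;
    dh.elem(find(cc.zh <= 0)).zeros();
    g.W3 += dh * cc.f.t();
    g.b3 += dh;
    vec df = net.W3.t() * dh;
    // unflatten (matches cc.f = vectorise(p2.t()))
    mat dp2 = reshape(df, cc.p2.n_cols, cc.p2.n_rows).t();
    mat dz2(C2, cc.o2 * cc.o2, fill::zeros);
    for (uword c = 0; c < (uword) C2; ++c)
        for (uword q = 0; q < dp2.n_cols; ++q)
            dz2(c, cc.arg2(c, q)) += dp2(c, q);
    dz2.elem(find(cc.z2 <= 0)).zeros();
    g.W2 += dz2 * cc.col2.t();
    g.b2 += sum(dz2, 1);
    mat dcol2 = net.W2.t() * dz2;
    cube dp1c = col2imCube(dcol2, cc.q1, cc.q1, C1, k);
    mat dp1(C1, cc.q1 * cc.q1);
    for (int c = 0; c < C1; ++c)
        dp1.row(c) = vectorise(dp1c.slice(c)).t();
    mat dz1(C1, cc.o1 * cc.o1, fill::zeros);
    for (uword c = 0; c < (uword) C1; ++c)
        for (uword q = 0; q < dp1.n_cols; ++q)
            dz1(c, cc.arg1(c, q)) += dp1(c, q);
    dz1.elem(find(cc.z1 <= 0)).zeros();
    g.W1 += dz1 * cc.col1.t();
    g.b1 += sum(dz1, 1);
}

struct AdamState {
    mat mW1, vW1, mW2, vW2, mW3, vW3, mW4, vW4;
    vec mb1, vb1, mb2, vb2, mb3, vb3, mb4, vb4;
    long t = 0;
};

template <typename T>
static void adamStep(T& w, const T& g, T& m, T& v, double lr, long t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    T mhat = m / (1 - std::pow(b1, (double) t));
    T vhat = v / (1 - std::pow(b2, (double) t));
    w -= lr * mhat / (sqrt(vhat) + eps);
}

// [[Rcpp::export(name = ".cnnTrain")]]
List cnnTrain(List params, const arma::cube& X, const arma::ivec& y,
              const arma::imat& batches, double lr) {
    Net net = unpack(params);
    AdamState st;
    st.mW1.zeros(size(net.W1)); st.vW1.zeros(size(net.W1));
    st.mW2.zeros(size(net.W2)); st.vW2.zeros(size(net.W2));
    st.mW3.zeros(size(net.W3)); st.vW3.zeros(size(net.W3));
    st.mW4.zeros(size(net.W4)); st.vW4.zeros(size(net.W4));
    st.mb1.zeros(net.b1.n_elem); st.vb1.zeros(net.b1.n_elem);
    st.mb2.zeros(net.b2.n_elem); st.vb2.zeros(net.b2.n_elem);
    st.mb3.zeros(net.b3.n_elem); st.vb3.zeros(net.b3.n_elem);
    st.mb4.zeros(net.b4.n_elem); st.vb4.zeros(net.b4.n_elem);
    const int steps = batches.n_rows, bs = batches.n_cols;
    vec losses(steps);
    Cache cc;
    for (int s = 0; s < steps; ++s) {
        Grads g;
        g.init(net);
        double loss = 0.0;
        for (int b = 0; b < bs; ++b) {
            const int idx = batches(s, b);
            mat x = X.slice(idx);
            loss += forwardImage(net, x, y(idx), cc, true);
            backwardImage(net, x, y(idx), cc, g);
        }
        const double sc = 1.0 / bs;
        st.t += 1;
        adamStep(net.W1, mat(g.W1 * sc), st.mW1, st.vW1, lr, st.t);
        adamStep(net.W2, mat(g.W2 * sc), st.mW2, st.vW2, lr, st.t);
        adamStep(net.W3, mat(g.W3 * sc), st.mW3, st.vW3, lr, st.t);
        adamStep(net.W4, mat(g.W4 * sc), st.mW4, st.vW4, lr, st.t);
        adamStep(net.b1, vec(g.b1 * sc), st.mb1, st.vb1, lr, st.t);
        adamStep(net.b2, vec(g.b2 * sc), st.mb2, st.vb2, lr, st.t);
        adamStep(net.b3, vec(g.b3 * sc), st.mb3, st.vb3, lr, st.t);
        adamStep(net.b4, vec(g.b4 * sc), st.mb4, st.vb4, lr, st.t);
        losses(s) = loss / bs;
        if (s % 50 == 0) Rcpp::checkUserInterrupt();
    }
    return List::create(
        Rcpp::Named("params") = List::create(
            Rcpp::Named("W1") = net.W1, Rcpp::Named("b1") = net.b1,
            Rcpp::Named("W2") = net.W2, Rcpp::Named("b2") = net.b2,
            Rcpp::Named("W3") = net.W3, Rcpp::Named("b3") = net.b3,
            Rcpp::Named("W4") = net.W4, Rcpp::Named("b4") = net.b4),
        Rcpp::Named("loss") = losses);
}

// [[Rcpp::export(name = ".cnnPredict")]]
arma::mat cnnPredict(List params, const arma::cube& X) {
    Net net = unpack(params);
    const int n = X.n_slices;
    mat probs(n, 4);
    Cache cc;
    for (int i = 0; i < n; ++i) {
        mat x = X.slice(i);
        forwardImage(net, x, 0, cc, false);
        probs.row(i) = cc.prob.t();
        if (i % 500 == 0) Rcpp::checkUserInterrupt();
    }
    return probs;
}
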