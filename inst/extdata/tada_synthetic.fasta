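>tada8e_synthetic synthetic stand-in; modern-state residues at the 8 divergence positions
MHMYAIKKDKTAHFYDALPWASCGAMWGGFLTSIKLHEWVRTCTMAIHTRPWYVHTCPSFNVLFDTSTEWDPWNGTASQWGVSGWCSSETRLCIRWIRAIWKVLGFHFSDRVWYDSRCNDGNMVARRTGLCILHWNTVDAWYICKYDWYDLFVGYCDPVIFPHKMIN
>tada710_synthetic synthetic stand-in; ancestral-state residues at the 8 divergence positions
MHMYAIKKDKTAHFYDALPWASCGAMWGGFLTSIKLHEWVRTCTMAIHTRPWYVHTCPSFNVLFDTSTEWDPWNGTASQWGVSGWCSSETRLCIRWIRAIWKVLGFHFADTVWYDSRCDDGHMVARRTGLCILHWNTVDAWYICKYYWFDLFVGYCDPVIFPHKMTD
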