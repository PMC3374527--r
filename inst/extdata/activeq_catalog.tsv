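activity_id	label	domain	met
occupation_rank_1	Mostly sitting	occupation	1.5
occupation_rank_2	A combination of sitting and standing up	occupation	2.3
occupation_rank_3	Mostly standing up	occupation	3.0
occupation_rank_4	Some physical activity	occupation	4.5
occupation_rank_5	Heavy manual labor	occupation	6.0
walking_transport	Walking	transportation	4.0
bicycling_transport	Bicycling	transportation	4.0
motorcycle_scooter	By motorcycle or scooter	transportation	2.5
car_taxi	By car or taxi	transportation	1.0
bus_train_subway_boat	By bus, train, subway, or boat	transportation	1.0
watching_tv	Watching TV/DVDs	leisure	1.0
using_computer	Using the computer	leisure	1.0
sitting_listening_music	Sitting listening to music, sewing, etc	leisure	1.0
musical_instrument_computer_games	Playing a musical instrument or active computer games	leisure	2.0
household_chores	Doing household chores	leisure	3.0
shopping_errands	Shopping or other errands	leisure	2.3
dancing	Dancing	leisure	3.0
walking_leisure	Walking	leisure	3.4
bicycling_leisure	Bicycling	leisure	8.0
aerobics	Aerobics	sport	6.5
weight_lifting	Weight lifting	sport	6.0
jogging_running	Jogging or running	sport	8.0
athletics	Athletics	sport	6.0
spinning	Spinning	sport	8.5
swimming	Swimming	sport	6.0
soccer_basketball_volleyball_floorball	Soccer, basketball, volleyball, or floorball	sport	6.0
golf	Golf	sport	4.5
dance_class	Dance class	sport	4.5
horseback_riding	Horseback riding	sport	4.0
ice_skating_hockey_bandy	Ice skating, ice hockey, or bandy	sport	7.0
skiing	Skiing (downhill or cross country)	sport	7.0
martial_arts	Martial arts	sport	10.0
boxing_wrestling	Boxing or wrestling	sport	6.0
tennis_badminton_squash	Tennis, badminton, or squash	sport	7.0
table_tennis	Table tennis	sport	4.0
rowing_canoeing_surfing_sailing	Rowing, canoeing, surfing, or sailing	sport	3.0
motor_sports	Motor sports	sport	4.0
rock_climbing	Rock climbing	sport	8.0
other_sport	Other	sport	2.5
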